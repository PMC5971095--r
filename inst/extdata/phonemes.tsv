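ipa	klass	aliases
p	consonant	
b	consonant	
t	consonant	
d	consonant	
k	consonant	
g	consonant	ɡ
m	consonant	
n	consonant	
ŋ	consonant	
f	consonant	
v	consonant	
θ	consonant	
ð	consonant	
s	consonant	
z	consonant	
ʃ	consonant	
ʒ	consonant	
h	consonant	
ʧ	consonant	tʃ
ʤ	consonant	dʒ
l	consonant	
r	consonant	ɹ
w	consonant	
j	consonant	
ɪ	vowel	
ɛ	vowel	e
æ	vowel	
ɒ	vowel	
ʌ	vowel	
ʊ	vowel	
ə	vowel	
i	vowel	
u	vowel	
iː	vowel	
uː	vowel	
ɜː	vowel	
ɔː	vowel	
ɑː	vowel	
eɪ	vowel	
aɪ	vowel	
ɔɪ	vowel	
əʊ	vowel	oʊ
aʊ	vowel	
ɪə	vowel	
eə	vowel	ɛə
ʊə	vowel	
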