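phoneme	class	place	manner	voicing	height	backness
P	consonant	bilabial	stop	voiceless	NA	NA
B	consonant	bilabial	stop	voiced	NA	NA
T	consonant	alveolar	stop	voiceless	NA	NA
D	consonant	alveolar	stop	voiced	NA	NA
K	consonant	velar	stop	voiceless	NA	NA
G	consonant	velar	stop	voiced	NA	NA
CH	consonant	postalveolar	affricate	voiceless	NA	NA
JH	consonant	postalveolar	affricate	voiced	NA	NA
F	consonant	labiodental	fricative	voiceless	NA	NA
V	consonant	labiodental	fricative	voiced	NA	NA
TH	consonant	dental	fricative	voiceless	NA	NA
DH	consonant	dental	fricative	voiced	NA	NA
S	consonant	alveolar	fricative	voiceless	NA	NA
Z	consonant	alveolar	fricative	voiced	NA	NA
SH	consonant	postalveolar	fricative	voiceless	NA	NA
ZH	consonant	postalveolar	fricative	voiced	NA	NA
HH	consonant	glottal	fricative	voiceless	NA	NA
M	consonant	bilabial	nasal	voiced	NA	NA
N	consonant	alveolar	nasal	voiced	NA	NA
NG	consonant	velar	nasal	voiced	NA	NA
L	consonant	alveolar	lateral	voiced	NA	NA
R	consonant	alveolar	approximant	voiced	NA	NA
W	consonant	labiovelar	approximant	voiced	NA	NA
Y	consonant	palatal	approximant	voiced	NA	NA
IY	vowel	NA	NA	voiced	high	front
IH	vowel	NA	NA	voiced	high	front
EY	vowel	NA	NA	voiced	mid	front
EH	vowel	NA	NA	voiced	mid	front
AE	vowel	NA	NA	voiced	low	front
AA	vowel	NA	NA	voiced	low	back
AO	vowel	NA	NA	voiced	mid	back
OW	vowel	NA	NA	voiced	mid	back
UH	vowel	NA	NA	voiced	high	back
UW	vowel	NA	NA	voiced	high	back
AH	vowel	NA	NA	voiced	mid	central
ER	vowel	NA	NA	voiced	mid	central
AY	vowel	NA	NA	voiced	low	central
AW	vowel	NA	NA	voiced	low	central
OY	vowel	NA	NA	voiced	mid	back
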