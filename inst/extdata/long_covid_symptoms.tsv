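symptom	freq_range
brain fog	8-60
chronic fatigue	15-87
asthma dyspnea	10-71
sleep difficulties	10-45
tachycardia	5-30
bowel irregularity	2-15
syncope	2-10
dizziness	3-20
difficulty walking	5-25
poor balance	3-15
muscle weakness	5-40
myalgia	5-50
frequent headaches	5-45
joint pain	5-30
cough	16
chest pain	14
congestion	10
sore throat	4
low-grade fever	4
whole-body pain	10-40
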