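symptom	freq_range
brain fog	83
chronic fatigue	87
asthma dyspnea	49
sleep difficulties	70
tachycardia	65
bowel irregularity	82
bloating reflux	79
syncope	30
dizziness	55
difficulty walking	35
poor balance	61
muscle weakness	60
myalgia	55
frequent headaches	60
joint pain	80
rashes	42
stretch marks	59
scoliosis	25
flat feet	46
sprains	56
whole-body pain	55
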