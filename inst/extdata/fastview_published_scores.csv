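"category","design","percent_agreement","kappa"
"Pavement width and obstructions","inter_rater",88.5,0.597
"Pavement surface quality","inter_rater",51.3,-0.009
"Kerb paving quality","inter_rater",82.7,0.373
"Road permeability","inter_rater",58.3,0.143
"Way finding and legibility","inter_rater",71.8,0.313
"Lighting","inter_rater",57.7,-0.075
"Personal security","inter_rater",79.5,0.445
"User conflict","inter_rater",89.1,0.451
"Environment quality","inter_rater",66.7,0.232
"Pavement width and obstructions","intra_rater",83.3,0.44
"Pavement surface quality","intra_rater",70,0.48
"Kerb paving quality","intra_rater",86.7,0.45
"Road permeability","intra_rater",73.3,0.48
"Way finding and legibility","intra_rater",86.7,0.66
"Lighting","intra_rater",86.7,0.6
"Personal security","intra_rater",86.7,0.42
"User conflict","intra_rater",90,-0.05
"Environment quality","intra_rater",66.7,0.3
"Pavement width and obstructions","criterion",85,0.69
"Pavement surface quality","criterion",83.3,0.73
"Kerb paving quality","criterion",75,0.55
"Road permeability","criterion",86.7,0.73
"Way finding and legibility","criterion",76.7,0.5
"Lighting","criterion",78.3,0.61
"Personal security","criterion",88.3,0.64
"User conflict","criterion",96.7,0.9
"Environment quality","criterion",86.7,0.62
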