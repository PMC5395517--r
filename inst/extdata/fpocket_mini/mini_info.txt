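Pocket 1 :
	Score : 	17.000
	Druggability Score : 	0.890
	Number of Alpha Spheres : 	6
	Total SASA : 	120.5
	Volume : 	311.250
	Mean local hydrophobic density : 	4.1
	Flexibility : 	0.22

Pocket 2 :
	Score : 	16.000
	Druggability Score : 	0.120
	Number of Alpha Spheres : 	4
	Total SASA : 	88.0
	Volume : 	154.700
	Mean local hydrophobic density : 	1.3
	Flexibility : 	0.41
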