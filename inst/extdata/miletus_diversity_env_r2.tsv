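index	altitude_r2	altitude_sig	temperature_r2	temperature_sig	latitude_r2	latitude_sig
theta_pi	0.152	ns	0.389	ns	0.538	ns
tajima_d	0.278	ns	0.577	ns	0.695	ns
ho	0.480	ns	0.708	ns	0.665	ns
he	0.576	ns	0.842	sig	0.883	sig
nei	0.566	ns	0.832	sig	0.860	sig
pic	0.533	ns	0.813	sig	0.864	sig
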