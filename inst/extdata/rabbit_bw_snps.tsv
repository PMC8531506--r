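chrom	pos	p_value	location
OCU2	7392553	1.06e-05	intron
OCU2	8791893	2.88e-05	intergenic
OCU2	10501993	3.52e-06	intergenic
OCU2	10591957	2.98e-07	intergenic
OCU2	11378860	2.94e-05	intron
OCU2	13386997	5.63e-06	intergenic
OCU2	13488329	3.69e-06	intergenic
OCU2	13770022	2.93e-05	intergenic
OCU2	13775984	9.13e-07	intergenic
OCU2	13847789	1.60e-06	intergenic
OCU2	13885731	2.86e-05	intergenic
OCU2	14218502	2.09e-05	intergenic
OCU2	14381825	1.39e-05	intergenic
OCU2	14388318	4.97e-06	intergenic
OCU2	15540704	8.39e-06	intergenic
OCU2	19348590	2.04e-05	intergenic
OCU2	19519932	3.07e-06	intergenic
OCU2	21766582	1.53e-05	intergenic
OCU2	21961157	2.03e-05	intergenic
OCU2	21961341	2.61e-06	intergenic
OCU2	21991030	8.43e-06	intergenic
OCU2	22076402	7.17e-06	intergenic
OCU2	22080992	2.06e-05	intergenic
OCU2	22082402	6.76e-06	intergenic
OCU2	22151345	3.50e-06	intergenic
OCU2	22287659	1.54e-06	intergenic
OCU2	22552417	5.98e-08	intergenic
OCU2	22559081	4.80e-07	intergenic
OCU2	22559709	2.22e-07	intergenic
OCU2	22559791	4.18e-06	intergenic
OCU2	22585579	2.37e-07	intergenic
OCU2	22597775	7.40e-07	intergenic
OCU2	22628803	6.92e-07	intergenic
OCU2	22632153	1.45e-06	intergenic
OCU2	22674072	4.67e-07	intergenic
OCU2	24405104	2.30e-05	intergenic
OCU2	31443212	1.89e-05	intergenic
OCU2	31466952	3.82e-07	3'-UTR
OCU2	58261249	2.21e-05	intergenic
OCU2	65306234	1.18e-05	intergenic
OCU2	65396063	1.74e-05	intergenic
OCU4	19121968	7.51e-08	intergenic
OCU9	35523218	1.48e-06	intron
OCU11	64951640	1.05e-05	intergenic
OCU19	52159278	1.15e-05	intron
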