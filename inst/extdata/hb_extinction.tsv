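# Molar extinction coefficients of oxy- and deoxyhemoglobin, 650-1000 nm.
# Basis: NATURAL LOG (Napierian), units mM^-1 cm^-1, i.e. tabulated log10-basis
# values in cm^-1/M (Gratzer & Kollias compilation, as redistributed by the
# OMLC spectra archive) multiplied by ln(10)/1000. The 650-850 nm band matches
# that compilation at its printed precision; the 860-1000 nm tail is a smoothed
# approximation of the same source adequate for forward simulation.
# Columns: wavelength_nm<TAB>HbO2<TAB>Hb
wavelength_nm	HbO2	Hb
650	0.847351	8.634694
660	0.735906	7.430442
670	0.67696	6.435725
680	0.639198	5.544625
690	0.635513	4.724905
700	0.66775	4.130838
710	0.723012	3.545981
720	0.8013	3.053228
730	0.898008	2.537449
740	1.026953	2.569685
750	1.224975	3.235132
760	1.349315	3.566704
770	1.49668	3.020992
780	1.634835	2.475279
790	1.782201	2.051603
800	1.878909	1.75457
810	1.989434	1.650954
820	2.109168	1.597994
830	2.242718	1.595691
840	2.353242	1.593389
850	2.436135	1.591086
860	2.514423	1.593389
870	2.597316	1.61181
880	2.657183	1.671677
890	2.712445	1.713123
900	2.758497	1.75457
910	2.809154	1.796016
920	2.84139	1.832858
930	2.8506	1.865094
940	2.795338	1.88812
950	2.772312	1.90654
960	2.721656	1.920356
970	2.657183	1.929566
980	2.578895	1.934171
990	2.500607	1.936474
1000	2.436135	1.938777
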