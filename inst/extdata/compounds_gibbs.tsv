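# Standard Gibbs energies of formation (kJ/mol) at reference temperatures (K).
# Synthetic reference table: derived from standard-state formation energies and
# enthalpies at 298.15 K via the Gibbs-Helmholtz relation; intended for worked
# examples and tests. Supply your own table for production use.
# name	phase	molar_mass	T1:dG1	T2:dG2	T3:dG3	T4:dG4
H2	gas	2.016	273.15:0.000	298.15:0.000	323.15:0.000	348.15:0.000
CO2	gas	44.01	273.15:-394.289	298.15:-394.360	323.15:-394.431	348.15:-394.503
CH4	gas	16.04	273.15:-52.740	298.15:-50.720	323.15:-48.700	348.15:-46.680
acetate	aqueous	59.04	273.15:-379.095	298.15:-369.310	323.15:-359.525	348.15:-349.739
H2O	liquid	18.015	273.15:-241.259	298.15:-237.180	323.15:-233.101	348.15:-229.021
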