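# Per-site free energies (kJ/mol) for proton translocation along the
# periplasmic and cytoplasmic water wires of E. coli AmtB, computed by a
# semi-macroscopic pKa approach on MD snapshots. z is the vertical
# coordinate (Angstrom) relative to the H168 sidechain; values are
# referenced to the periplasmic bulk water site wat1 (0.0). wat1 sits in
# the periplasmic bulk; D160 lies between wat5 and wat6, the twin-His
# motif (H168) below wat8, and H318 beside wat12 near the cytoplasmic
# exit.
label	wire	z	free_energy_kj_mol
wat1	periplasmic	14.7	0.0
wat2	periplasmic	12.7	8.7
wat3	periplasmic	10.7	15.0
wat4	periplasmic	8.3	14.4
wat5	periplasmic	6.1	7.5
wat6	periplasmic	5.4	11.0
wat7	periplasmic	3.2	14.4
wat8	periplasmic	0.6	18.5
wat9	cytoplasmic	-0.4	17.3
wat10	cytoplasmic	-0.8	14.4
wat11	cytoplasmic	-3.2	12.1
wat12	cytoplasmic	-5.1	13.8
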