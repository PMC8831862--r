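gene	cdna_hgvs	protein_hgvs	class	source
COL1A1	c.2461G>A	p.Gly821Ser	missense	cohort
COL1A1	c.2299G>A	p.Gly767Ser	missense	cohort
COL1A1	c.590G>A	p.Gly197Asp	missense	cohort
COL1A1	c.3803A>T	p.Asp1268Val	missense	cohort
COL1A1	c.1054G>A	p.Gly352Ser	missense	synthetic
COL1A1	c.1762G>C	p.Gly588Arg	missense	synthetic
COL1A2	c.650G>A	p.Gly217Asp	missense	cohort
COL1A2	c.1072G>A	p.Gly358Ser	missense	synthetic
COL1A2	c.1991G>T	p.Gly664Val	missense	synthetic
COL1A2	c.2756G>A	p.Gly919Asp	missense	synthetic
COL1A1	c.805-2A>G		splicing	cohort
COL1A1	c.1845+1G>A		splicing	synthetic
COL1A1	c.1279delG		frameshift	synthetic
COL1A1	c.2005dupC		frameshift	synthetic
COL1A1	c.3076C>T	p.Arg1026Ter	nonsense	synthetic
COL1A2	c.792+2T>G		splicing	cohort
COL1A2	c.1665+2T>C		splicing	synthetic
COL1A2	c.2943delT		frameshift	cohort
COL1A2	c.3105dupC		frameshift	synthetic
COL1A2	c.1984_1986del		other	synthetic
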