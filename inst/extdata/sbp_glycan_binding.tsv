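# Glycan-array binding specificities of three B. longum SC596 solute-binding
# proteins (family 1 SBPs screened on the CFG mammalian glycan array v5.1):
# IUPAC-condensed glycan string with spacer suffix, and the published average
# RFU (six replicates, highest and lowest removed before averaging).
sbp	glycan_string	rfu
BLNG_00160	Galβ1-3Galβ1-4GlcNAcβ-Sp8	4654
BLNG_00160	Galβ1-3GalNAcβ1-4Galβ1-4Glcβ-Sp8	3430
BLNG_00160	Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-6(Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-2)Mana1-6(Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-2Mana1-3)Manβ1-4GlcNAcβ1-4(Fuca1-6)GlcNAcβ-Sp24	3351
BLNG_00160	Neu5Acα2-6(Galβ1-3)GlcNAcβ1-4Galβ1-4Glcβ-Sp10	2706
BLNG_00160	Galβ1-3(6S)GlcNAcβ-Sp8	2646
BLNG_00160	Galβ1-3GalNAcβ1-3Gal-Sp21	2528
BLNG_00160	Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-3Galβ1-4GlcNAcβ1-6(Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-3Galβ1-4GlcNAcβ1-2)Mana1-6(Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-3Galβ1-4GlcNAcβ1-2Mana1-3)Manβ1-4GlcNAcβ1-4(Fuca1-6)GlcNAcβ-Sp24	2513
BLNG_00160	Galβ1-3GalNAcβ-Sp8	2338
BLNG_00160	Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-6(Galβ1-3GlcNAcβ1-3)Galβ1-4Glcβ-Sp0	2212
BLNG_00160	Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-2Mana1-6(Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ1-2Mana1-3)Manβ1-4GlcNAcβ1-4GlcNAc-Sp25	2079
BLNG_00160	Galβ1-3GlcNAcβ1-3Galβ1-4GlcNAcβ-Sp0	2029
BLNG_00160	Galβ1-3GlcNAcβ1-3Galβ1-4Glcβ-Sp10	1784
BLNG_00160	Galβ1-3Galβ-Sp8	1508
BLNG_00160	Galβ1-3GlcNAcβ-Sp0	969
BLNG_00936	Galβ1-3GalNAcβ-Sp8	303
BLNG_00936	Galβ1-3Galβ1-4GlcNAcβ-Sp8	126
BLNG_01257	Fuca1-2Galβ-Sp8	2161
BLNG_01257	Fuca1-2Galβ1-4Glcβ-Sp0	360
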