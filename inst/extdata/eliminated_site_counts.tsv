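category	mac_contigs	total_sites	sites_with_eccdna
non_scrambled	15680	119613	555
scrambled	2818	10151	4
intergenic	NA	16846	17
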