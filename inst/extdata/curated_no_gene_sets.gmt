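ETC_COMPLEX_I	NADH:ubiquinone oxidoreductase (complex I) subunits	Ndufa1	Ndufa2	Ndufa3	Ndufa5	Ndufa6	Ndufa7	Ndufa8	Ndufa9	Ndufa10	Ndufa11	Ndufa12	Ndufa13	Ndufb2	Ndufb3	Ndufb4	Ndufb5	Ndufb6	Ndufb7	Ndufb8	Ndufb9	Ndufb10	Ndufb11	Ndufs1	Ndufs2	Ndufs3	Ndufs4	Ndufs5	Ndufs6	Ndufs7	Ndufs8	Ndufv1	Ndufv2	Ndufv3	mt-Nd1	mt-Nd2	mt-Nd3	mt-Nd4	mt-Nd4l	mt-Nd5	mt-Nd6
ETC_COMPLEX_II	succinate dehydrogenase (complex II) subunits	Sdha	Sdhb	Sdhc	Sdhd
ETC_COMPLEX_III	ubiquinol-cytochrome c reductase (complex III) subunits	Uqcrc1	Uqcrc2	Uqcrfs1	Uqcrb	Uqcrq	Uqcrh	Uqcr10	Uqcr11	Cyc1	mt-Cytb
ETC_COMPLEX_IV	cytochrome c oxidase (complex IV) structural subunits	Cox4i1	Cox4i2	Cox5a	Cox5b	Cox6a1	Cox6a2	Cox6b1	Cox6c	Cox7a1	Cox7a2	Cox7b	Cox7c	Cox8a	Ndufa4	mt-Co1	mt-Co2	mt-Co3
ETC_COMPLEX_V	ATP synthase (complex V) subunits	Atp5a1	Atp5b	Atp5c1	Atp5d	Atp5e	Atp5f1	Atp5g1	Atp5g2	Atp5g3	Atp5h	Atp5j	Atp5j2	Atp5k	Atp5l	Atp5o	mt-Atp6	mt-Atp8
COX_ASSEMBLY	cytochrome c oxidase assembly chaperones	Cox10	Cox11	Cox15	Cox17	Cox19	Cox20
MT_ENCODED	mitochondrially encoded genes	mt-Nd1	mt-Nd2	mt-Nd3	mt-Nd4	mt-Nd4l	mt-Nd5	mt-Nd6	mt-Cytb	mt-Co1	mt-Co2	mt-Co3	mt-Atp6	mt-Atp8
DENITROSYLASES	denitrosylase and redox-relay enzymes	Ahd5	Txn1	Txn2	Txnrd1	Txnrd2	Grx1	Grx2	Grx3	Grx5	Glrx	Glrx2	Trp14	Txndc17	Apex1	Prdx1	Prdx2	Akr1a1
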