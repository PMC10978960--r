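>SacSAHH
DNFSMTGAHPEQHIYFSRNICWLLPCNLQNDGACWDIMWNKGCEHKVPFDHSTVEVKFPLPWIHHYWGDM
QLYQFSCWSEKKRFPVNIYTQHPSCGFPKPSMWFWLDAAPPFCGPPYHFNCICDYWTIKHDVRDAKMFAQ
WYEAVSFNFKFFRVRDSVRWLDDGMSILTSNIRAYEMKMMGSHARCAYQKREMLCHMNYPQCGCETDQWN
YHMAHIDLVGMLMTEFTFTSAVKRCVGNCDRGASKVECLSLMSWGNRMTYKESTQHSLHAYACCYSYGLM
FRFVPMSFRERYIHFRIEACWDWKLKQKEIRPVTEGKIRRATVHHLMNYTHHHPIVSSAIWEMHTPYFYM
VVMRFMSQINMMCWEVDDRRTCSGTEKYKFIQWHPGSSVNMMIQGHRPMI
>SsoSAHH
DNFSMTGAFPEQHIYFSRNICWLLPCNLQNDGTCWDIMWNKGCEHHVPFDHSTVEVKFPLPWIHHYWGDM
QLYQFSCWSEKKRFPVNICTQGPSCGFPKGSMWFWLDAAPIFCGPSYHFNCICDYWTIKHDVGDAFMFAQ
VYEAVSFNDKFYRVRDSTRWLDDQMRILTSNIRAYVMKMMGSHARYAYQKREMLCHMNYPECGCETDQWN
YHMTHIDLVGMLMTEFTFTSAVKRCVGNCDRGASKVECHSTMSWGNEMTYKESTDHSLHAYACCYSYGLM
FRFVPMSFRERYTHFRIEACWDWKLKQKEHRPVTEGKIRKADSEHLMNYTHHHPICSSAIWEMHTPYFYM
VVMRFMSHENHQCWEVDDRRTCRGTEKYKFIQWHPGSSVNMLKQGHRMMI
>McSAHH
DNFSMKGAFTAERPEVHIYFSRNICWLLPCNLQNDGAIWDVMISKGCERKCPFDHSTVEVEFPLPWIHNY
GGDMQLYQFSCWSEKKRFPVNIQNQHPSCGFKKGSMWFWLDAAPPFCIPPYKFNCICDYWTIKHDVGDAF
WFAQWYEAVSSNFAFFRVRDSVRWLDDAMSILRSNIRAYEMKMMGSHARCAYQRREMLCHMNYPQCGCET
DQWNYHMQHIDPHAMLMTEFTVTSARKRCVGNLDHGASKCECHSTGSWREQMTYKESTQHSLHAYACCYS
YGLMFRFVPMSFRERYTHFRDEDCWDWKLKQKEIRPWTEGKIRKADSEHLMNYTTCHPIWSSAIWRMDTP
YFYMVHRRFMLHEIHQCWEVDDCRTCSMTEKYKFIQWGYRSSVNMLIQGHRMMI
>MeSAHH
DNFSMKGAFTAEIPEVHIKFPRNICWLLPCNDQADGGITDVMINKGCERKCPFDHSTVEVKFPLPWIHNY
GGDMQLYQFSCWSEKKRAAVNIYTQHPSCGFKKGSMWFWLDLARPWCGPPYKFNCICDYWTIKHDVGDAF
WFAQWCEAVSKKMYMSQQSYRAKDFDALPAYFSYIAQGNSFGIEFTTKLGFNFAFFYVRDSVRWLDDPFS
ILRSNIRAYEMKRMGSVARCAYQRREMLVHMNYPQCGCEPDQWNYHMQCINLLIMLITEFTVTSAHKRCV
GNCDHGASKVYCQSTMSWGERMTYKELTQHSLWAYACCYSYGLMFRVVHMSTRERYTHFRIECCVDWKGK
QKEIRPVTEGKIRTADSEHLMNYTHCPPIISSAIWRMDTPYFYMVHMRFMAHENVQCWEVDSVRTCSMTE
KYKFSQWGYRSSVGMYIQGHRMMACSKWFPCWFLVSQGMAWWPTPRRHT
>MhSAHH
DKFSMFGAFTAEIPEWHIKFPRNICWLLPCNLQNDGGIWDVMIYKGCERKCPFDHSTVEHKFPLLWIHNY
GGDMQLYQFSCWSEKKRFAVNIYTQHPTCGFKKGSMWFQLDLAPPFCGPPYKFNCICFWWTGKHDVGDAF
WFAQWCERVSKKMYMSQQSYRAKDFDALPAYFSYIAQGNSFGIEFTTKLGFNFAFFRVRDSVRWLDDPMS
ILASNIRAYEMKRMGSVARCAYQRREMLVHMNYPQCGCEPDQWNYHMQCINLLIMLMTEFKVTSAHKRCV
GNCDHGASKVDCHSQMSWGERMTYKELTQHSLHAYACQYSYGLMFRVVPMSTRERYTHFRIECCWDWKLK
QKEIRPVTEGKIRIADSEHLMNYTHCPPICISAIWIMDTPYYYMVHMRFMLHENVQCWEVDSVRTCSMTE
KYKFIQWGYRSSVGMYIQGHRMMACSKWFPCWFLVSQGMAWWMFPRRHT
>MiSAHH
DNFSAKGAFTAEIPEVHHYFSRIICWLLPCNLQNDGAIWDVMINKGCERKCPFDHSEVKVKFPLPWAHNY
GGDMQLYQFSCWHEKKRFPVNIYTQHKSCGFKKGSWSFWLDYAPKFCGPPYKFNCICDYWTIKHDVGDAF
WFAQWYEAVSFNFAFFRVRDSVRWLDDAMSILRSNIRAYEMKMMGSHARCAYQRREMLCHMDYPQCGCET
DQWNYHMQHIDVHAMLMTMFTVTSARKRCVGNSDHGASKVECHSTMSWGEWMTYKESTQHSLHAYACCYS
YGLMPRFVPMSFRERYTHFRIEDCWDWKLKAKEIRPVTEGKIRKADSEHLMNYTHCHPICSSAIWRMDPP
YFYMVHMRFMLHTNHQCWEVDDRRTCSMTEKYKFKQWGYRSSVNMLIQGHRMMI
>MjSIHH
DNPTMKGAFTAEIPEVHIYFSRNICWSLPCNLQNDGAIWRVMINKGCERKWPFDHSEVKVKFPLPWIHNY
GGDMQLYQFSCTSEKKRFPVNIYTQHPSCGFKKGSMWFWLDAAMPFCGPPYKFNCICDYWTIKHDVGDAF
WFAQWYEAVSFNFAFFRVRDSVRWLDDAMSILRSNIRAYEMKMMGSHARCAYQRREMLGHMNYPQCGCET
DQWNYHMQHIDLHAMLMTEFTVTSARKRCVGNCDHGASKVQCHSTMSWGARMTYKESTQHSLHAYACSYS
YGLMFRFVPMSFRPHYTHFAIEDCWDWKLKQKEIRPWTEGKIQKADSEHQMNYTHCHPICSSAIWRMDTP
YFYMVHMRFMLHENHQCWEVDDRRTCSATEKYKFIQWGYRSSVNMEIQGHRMVI
>MmaSAHH
DNFSVKGAFTAEIPEQHIYFCYQFFCIVVGNFHSPSRNICWLLPCNQQNDGAPPSVMINKSCERKCPLDH
SEVKVKFPFPWIDNYTGDMQLAQFSCWSESKRFPVNIETQHPSCGFKKGSMWFWLDAAPRFYGPPYAFNC
ICDYWTIKHDVGPAFWQAQWYEAVSFNFAFFDVRDSVRWLDDAMSILRSYIRAYEMKMMGSHARCAYQRR
FMLCHMNYPQCGCSTDYWNYHMQHIDLHAMLLTEFTVTSRKRCTGNCDHGASKVDCHCTMSWKERMTYKE
STQHCLHAYVCCYSYGLMFRFVPMSFRYRYQHFRIEDCWDWKLKQKEIYPVTLGKIRKADSETLMPYTHC
HPICSSAIWRMDTPYFDMEHMHFMLHEFHQCWEVDARRTCSMTMKYKFIWWGARSSFNMLRQGHRMMI
>MtSAHH
DNFSMKGGFTAEIPEVHIYFSRNICWLLPCNLQNDGAIWDVMINKGCERKCPFDHSTVEKVFPLPWIHNY
GGDMQLYQFSCWSEKKRFPVNIYTQHPSCGFKKGSMWFWLDAADPFCGPPYKFNCICDYWTIWHDVGDAF
WFKQWYEAVSFNFANFRDRDSVRNFDDAMSILRSNIRAYENFMMGSHARCAYQRREMLCHMNYPQCGCET
DQWNYHMQHIDLWAFLMTEFTVTSARKSCVRNCDHGDSKVECHSTMSWGEDMTYKESTQHSLHAYAMCYS
YGLMFRFVPMSFRERYTHFRIEDCWDWKLKQKEIRPVTEGKIRKADSEHLMNYTHCHPICSSAIWRMDTP
YFYMVHMRFMLHENHQCWEVDDRGTCSMTEKYKFIQWGYRSSVNMLIQGHRMMI
>PfuSAHH
VNFSMKGAFTAEIPEVHIYFVRNICWLLPCNLQNDGAINDVMINKGCERKCPFDHSEVKVKFPLPWIHNY
GGDMQLYQNSCWSEKKRFPVNIYTQHPSCGPKKGSMWFWLDAAPPFCGPPYKFNCIIRYWTIKHDVGDAF
WFAQWYEAVSFNFAFFRVRDSVRWLMDAMSILRSNIRAYEMKMMGSHARLAYQRREMLCHMNYPQCGCET
DQWNYHMQHIDLEAMLMKEFTVTSPRKRCVGNCDHGASKVECHSTMSWGERMTYDESTQHSLHAYACCYS
YGLMFRFVPMSFRERYTHFRIEDCWDWKLKQKEIRPVTEGKIRKADSEHLMNYFHCHPICSSMIWRKDTP
YFYMVHMRFMLRENHQCVEVDDRRTCSRTEKYKFIQAGYRSSVNMLIQGHRMMI
>TkSAHH
DNFSMKGAFTAEIPEVHIYFSRNICWLLPCNLQNDGAIWDVMINFGCERKCPFDHSEVKVKFPLPWIHNY
GGDHQLGQGSCWSEKKRFPVNIYTKHPSCGFKKGSMWFWLDAAPPFCQPPYKFNCICDYWTIKHDVGDAM
WFAQWYETVSFNFAFFRVRDSVRWLDDFMSILRSNIRAYLMKMMGSHARCADQRREMLCHMNYPQCGCET
DQWNYHAQHIDLHAMLMTEFTVTSARKRCVGNCDHGASKVECHSTWSWGERMTYKESTQHSLHAYACCYS
YGLMFIEVPMSFRERYTHFRIEDCWDWKLKQGEIRPVTEGKARKADSEHLMNYTHCHPICESAIWRMDTP
YFYMVHMRFMLHENHQCWEVDDRGTCSMTEKYKFIQWGYRSSVNMLIQGHRLMI
>CgSAHH
DNFSMSGAFMAEIPEVHIKFPRNICWLLCCNLQNDGGIWDNMINSGCERKCPFDHSTVQVKFPLPWIHNY
GGDMRLYQFSCWSEKKRFAVKIYTQHPSCDIKKGAYWFWLDLAPFFCGPPYKFNCICDYWRIKHDVGDAF
WFAQWCEAVSKKMYMSQQSYRAKDFDALPAYFSYIAQGNSFGIEFTTKLGFNFAFFRVRDSVRWLYDPMS
ILRSNIRAYEMKRMGSVHRCAYQRREMLGHMNYPQCGCEPDQWNYHMQCINLLIMLMTNFTVTSAHKRCV
GNCDHGASKVDCHSTMSWGERMTYKELTQHSLHAYACCYSYGLMFRVVPMSTRERYTHFRIECCWDWKLK
QKEIRPVTEGKIRIADSEHLMNYTHCPPICSSAIWRMDTPKFYMVHMRFMLHENVQCHEVDSVRTCSMTE
KYKFIQCGYRSSVGMYIQGHRMMACSKWFPCWFLVSQGMAWWMTPRRHT
>PaSAHH
DNFSMKGAMTAEIPELHIKIPRNICWLLPCNLQNDGGIWDVMINKGCERKCPFDHSTVQIKFPLPWIHNY
GGDMQLYQCSCWSEKKRFAVNIYYQHPKCGFWKYSMWFWLDLAPPFCGPPYKFNCIRDYWTIKHDVGDAF
WFAQWCEAVSFNLAFFRVRDSVRWLDDPMSIQRSNIRAYEMKWMGSVARCAYQRREMLVHMNYPQCGCEP
DQWNYHMQCINLLIYLMTEFTVTSAHKRCVGNCDHGASKVDCHETMSWGERMTYKELTQHSLHALACCYS
YGLMFRVVPMSTRERYTHFRIMCCWDWKLKQKEIRPVTEGKIRIADSEHLMNYTHCPPICSSAIWRMDTP
YFYMVHMRFMLHCNVQCWPVDSVRTCSMTEKYKFIQWGYRSSVGMYIQGHRMMACSKWFPCMFLVSQGMA
WWMTPRRHT
>SaSAHH
DNFSMKGAFTAEIPEAHIKFPRNICWLLKCNLTNDGGIWMVMINYGCERKCPFNHSTVQVKFQLPWIHNY
DGDMQLYQFQCWSEKKRFAVNIYTQHPSCGFKKGSMWFWQDLAFPFCGPPYKFNCICDYWTIKHDVGDAF
WFAQWCEAVSKKMYMSQQSYRAKDFDALPAYFSYIAQGNSFGIEFTTKLGFNFAFFRVRDSVRWGDDPMS
ILRSNIRAYEMKAMGSVARCAYQRREMLVHMNYPQCGCEPDQWNYHMQCINLLIMLMTEFLVTSAHKRCV
GNCDHGASKVDCGSTMSWGERMTYKEYTQHSLHAYACCYSYGLMFRVVPMSTRERYTHFRIECCWDWKLD
QKEIRPVTEGKIRIADSEHLMNYTHCPPICSSAIWRMDTGYFYMVHMRFMLHENVQCWEVDSVRTCSMTE
KYKFIQWGYWSSVGMYIQGHRMMACSKWFPCWFLVSQGMAWWRTPRRHT
>SfSAHH
DNFSMKGAFTAEIPEVHIKFPRNICWLLPCNLQKDGGIWDVMINKGCERKCPFDHSTVQVKFPLPWTHNY
GGDMQLYQFSCWSEKKRFALNIETQHPSCGFTKGSMWFWLKLAPPFCGPPYKFNCICDYWTIKHDVGDAE
WFAQWCEAVSKKMYMSQQSYRAKDFDALPAYFSYIAQGNSFGIEFTTKLGFNFAFFRVRDSVRWDDRPMS
ILRSNIRAYEMKRMGSVARCAYERREMLVHMNYPQCGCEPDQWNYHMSCINRLIMLMTEFTVTSAHKRCV
GNCDHGASKVDCHSTMSWGERMTYKELTQHSLHAYACCYSYGLMFRVVPMSTRERYTHFRIEACWDWKLK
QKEIRPVTEGKIRIADSEHLMNYTHCPPECSSAICRMDTPYFYMVHMRFMLHENVQCWENDSVRTCSMTE
SYKFIQWKYRSSVGMYIQGHRMMACSKWFPCKFLVAQGMAWWMTPRRHT
>TmSAHH
DNFSMKGAFTAEIPEVHIYFSRSICWLLPCMLQNDGAIWDVMINKGCERKCPFDHSEVKVKFPLPWIHNY
GGDMQLYQFSCWSEKKRFPVNIYTQHPSCGFKKGSMWFGLDAAPPFCGPPYKFNCICDYWTIKHDVGDAF
WFAQWYEAVSFNFAFFRVRDSVRWLCDAMSILRSNIRAYEMSMMGSHARCAWQRREILCHMNYPQCGCET
DQWNYHMQHIDLIAMLMTEATVTSARKRCVSNCWHGACKVECHSTMSWGERMTYKESTQHSLHAYACCYS
YGLMFRFVPMSFRERYTHFQIMDCWDWKLKQKEIRPVKEGKILKADSEHLMNYTHCHPICSSAIWRMDTP
YFYMVHMRFMLHWNHQCWEVDDRRTCSMTMKYKFIQWGYRSSVNMVIQGMRMMI
>LlSAHH
DNFSMKGAFTAEIPEVHIKFPRNICWLLPCNLQNMGGIWDVMINKGCERNCPFDHSTVQVKFPLPWIHNY
GGDMQLYQFSCYKEKKRFAVNIMTQHPSCGFKKGSMWFWWDEAPPFCGPPYKFNCICDYWTIKHNVFDAF
WFAQWCEAVSKKMYMSQQSYRAKDFDALPAYFSYIAQGNSFGIEFTTKLGFNFAFFRVRDSVRWLDDPMS
ILRSNIREYEMKRMGSVARCAYQRREMLVHMNYPQCGCEPDQWNYHMQCINLHIMLMTEFTVTSAHKRCV
GNCDHGASKVDCHSTMSWGERMTYKELTQHSTHAIACCYSYGLMFRVVHMSTRERYTHFRIECCWDWKLK
QKEIRPVTEGKIRIADSEHLMNYTHCPPICSSAAWRMDTPYFYMIHMRFMLHEQVQCWEVDSVRTCSMTE
WYKFIQWGYRSSVGMYIQGHRMMACSKWFPCWFRVSQGMAYWMTPRRHT
>MmSAHH
DNFSMKGAFTAEIPEVHIKFPRNICWLLPCNLQNDGGIWDVMINKGCERKCPFIHSTVQVKFPLPWLHNY
GLDMQLYQFSCWSEKKRFAVNIYYQHPSCGFKKGSMWFWLDLAPPFCGPPYKFNCICDYWTIKHDVGDAF
WFAQWCEAVSFNWAFFRVRDSVRWLDDPMSIIRSNIRAMEMKRMGSVARCAYQRREMLVAMNYPQCGCEP
DQWNYHMNCINLLIMLMTEFTVTSAHKRCVGNCDHKASKVDCHSTMSWGYRMTYKELTQHSEHAYACCYS
YGLMFRVVPMSTRYRYTHFRIECCWDWKLKQKEIRPVTEGKIRIADSDHLMNYTHCPPICSSAIWRMDTP
YFYMVHMRFMLHENVQCWEVDSVRTCAMTEKYDFIQWGYRSSVGMYIQGHRMMACSKLCPCMFLVSDGMA
WWMTPRRHT
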