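>PfuSAHH_like
DNFSMKGAFTAEIPEVHIYFSRNICWLLPCNLQNDGAIWDVMINKGCERKCPFDHSEVKVKFPLPWIHNY
GGDMQLYQFSCWSEKKRFPVNIYTQHPSCGFKKGSMWFWLDAAPPFCGPPYKFNCICDYWTIKHDVGDAF
WFAQWYEAVSFNFAFFRVRDSVRWLDDAMSILRSNIRAYEMKMMGSHARCAYQRREMLCHMNYPQCGCET
DQWNYHMQHIDLHAMLMTEFTVTSARKRCVGNCDHGASKVECHSTMSWGERMTYKESTQHSLHAYACCYS
YGLMFRFVPMSFRERYTHFRIEDCWDWKLKQKEIRPVTEGKIRKADSEHLMNYTHCHPICSSAIWRMDTP
YFYMVHMRFMLHENHQCWEVDDRRTCSMTEKYKFIQWGYRSSVNMLIQGHRMMI
>SacSAHH_like
DNFSMTGAFPEQHIYFSRNICWLLPCNLQNDGACWDIMWNKGCEHKVPFDHSTVEVKFPLPWIHHYWGDM
QLYQFSCWSEKKRFPVNIYTQHPSCGFPKGSMWFWLDAAPPFCGPPYHFNCICDYWTIKHDVGDAFMFAQ
WYEAVSFNFKFFRVRDSVRWLDDAMSILTSNIRAYEMKMMGSHARCAYQKREMLCHMNYPQCGCETDQWN
YHMTHIDLVGMLMTEFTFTSAVKRCVGNCDRGASKVECHSTMSWGNRMTYKESTQHSLHAYACCYSYGLM
FRFVPMSFRERYTHFRIEACWDWKLKQKEIRPVTEGKIRKADSEHLMNYTHHHPICSSAIWEMHTPYFYM
VVMRFMSHENHQCWEVDDRRTCSGTEKYKFIQWHPGSSVNMLIQGHRMMI
>MmaSAHH_like
DNFSVKGAFTAEIPEVHIYFCSQFFCIVVGNFHSPSRNICWLLPCNQQNDGAIVSVMINKSCERKCPLDH
SEVKVKFPFPWIHNYTGDMQLAQFSCWSEKKRFPVNIYTQHPSCGFKKGSMWFWLDAAPRFCGPPYAFNC
ICDYWTIKHDVGDAFWFAQWYEAVSFNFAFFRVRDSVRWLDDAMSILRSYIRAYEMKMMGSHARCAYQRR
FMLCHMNYPQCGCETDYWNYHMQHIDLHAMLMTEFTVTSRKRCTGNCDHGASKVDCHCTMSWKERMTYKE
STQHCLHAYACCYSYGLMFRFVPMSFRERYQHFRIEDCWDWKLKQKEIYPVTEGKIRKADSETLMPYTHC
HPICSSAIWRMDTPYFDMVHMHFMLHENHQCWEVDARRTCSMTMKYKFIWWGARSSVNMLIQGHRMMI
>LlSAHH_like
DNFSMKGAFTAEIPEVHIKFPRNICWLLPCNLQNDGGIWDVMINKGCERKCPFDHSTVQVKFPLPWIHNY
GGDMQLYQFSCWSEKKRFAVNIYTQHPSCGFKKGSMWFWLDLAPPFCGPPYKFNCICDYWTIKHDVGDAF
WFAQWCEAVSKKMYMSQQSYRAKDFDALPAYFSYIAQGNSFGIEFTTKLGFNFAFFRVRDSVRWLDDPMS
ILRSNIRAYEMKRMGSVARCAYQRREMLVHMNYPQCGCEPDQWNYHMQCINLLIMLMTEFTVTSAHKRCV
GNCDHGASKVDCHSTMSWGERMTYKELTQHSLHAYACCYSYGLMFRVVPMSTRERYTHFRIECCWDWKLK
QKEIRPVTEGKIRIADSEHLMNYTHCPPICSSAIWRMDTPYFYMVHMRFMLHENVQCWEVDSVRTCSMTE
KYKFIQWGYRSSVGMYIQGHRMMACSKWFPCWFLVSQGMAWWMTPRRHT
>MjDadD_like
ARMIYQYTLDGKWPIQYIMIQTMRSGWGMPHKVVAKKAFEFFKCDYQKMHSEFDRVYMDTFANDHVQKLE
LCQAHYVPQWRLNAYHDNMTCWKKVEESLWCGYFGMMEQCCKNYLNCWLCCGAVIYIGLKGVWEHKYSII
AFIDQFIPGEGPPDDAHCYHVCYMSLRCTMWMIAAINNWWIEINHPSDVWEATGNQPCFKPTSAAAILWE
DHQQNCQHERTMKTSTKCFWHFYDQAIDMFMSMTFDYDLCGWDYWCAHNMISMHHVLDHHACTGAVMHGC
TYWWNLTKSVCDMFHLKMVCHDSTFFYQVQMVCYPGCDLPYTQGISLCYDSHQHPELAVPWGMLDNNDKV
EQGQNWIYWESFDFNFNEMHEAPCFCRYPACIDYIGWCQCNFKVVGHHPIVLICHGHLGSKFMPYPSHTR
TSGPPIAGATYNIASDRQDM
>EcMTAN_like
VIANRHPHLRATLGYFQEVSSWIDAHIEFTWMRKFIFCVYPQMNLKIPMWQVAKYPLEDWFKNVDEQPWA
CISPEEGLMTHTKWSWPLIPLEDKLYQAVLEPHMERQTYWGTQGVGYSLHDDRRFVTLADINAYITNPCC
TARGYSRGSMLICPTKYDTYVLLLEGPKHQCPSFVMMHEWCSINNLSMPFALMNNKNSMPQQVNPVYAGT
MWVAPVQITENPVQNQLTCKEP
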