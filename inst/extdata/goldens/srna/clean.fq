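@sim:000001
CGTTTAGCGCCAAAGTCTGTGTCACA
+
HFA@CEH=>GD@CD@GICF>DFCHAC
@sim:000002
TTGCACTAGGTAGCCTTGCC
+
DI@FH@DCDDCEEEGG:CFD
@sim:000004
GAAATACACTGTTATTGGTCATGAGG
+
AAFDDICBHFDE?DEHGDEDEDFFCD
@sim:000005
CAATGTGGTGGAGTGAGTACAGATCGTACA
+
GGHD@@BECCEDDIAIFCBFAI?FDD>BID
@sim:000006
GCTCTTCATCAATGATAATCTGGGCGAAA
+
HBEBFCI@FED=DGFDFDA?CB@<EDECG
@sim:000008
ACTTAACTTAGCAATTCAGCGGAGGTTTAG
+
BCFFCCFEIC@@F@HB@EEDBBD=FGEBDE
@sim:000009
CTGTCGTCTGCTAGCACGTAG
+
@FGCBCE>CACAJEEIECDDD
@sim:000010
TACTAGAACGTGCGCCCG
+
EC?DADBF@?EGBFFDBF
@sim:000011
ATGAAATAGATTCGTCCCGTCGTGG
+
FA?D>FBFCCFHGBADBIFCGE?F=
@sim:000012
CACAGCGCTTCGACCACC
+
CGGEDACHDDFEAEDGEC
@sim:000013
AATTCGAACCAGCTACCCT
+
CBCDCEFJJ@ACFDCFBEH
@sim:000014
TCGGGATCTTAGTTACTAATGAG
+
B?DABD@@EH@@FJBDIGEEHCA
@sim:000016
TGGGAAGAGAGCCGTGATTAAGTCCAA
+
DGHFBC@BGFBDAA@BD?@J@HI@CG@
@sim:000017
AGTGTAACTTTGTATAAGATAGTAA
+
<AHFCFHIBF>FC?IDGBEJDBEDB
@sim:000018
AAAAGTTGTGATGAATTTCCGTGGACACCA
+
AFBFEDDBCD<FGGGB@AFDDDDD;EAFEE
@sim:000019
CTACTTTACAAGCAGTACGAATTTACCATT
+
@BFBCEJFHD?DJDHIFAAAEIGHBAH@ED
@sim:000022
TTGCATGGTGTGCCCACGCCAGACCGCAC
+
@>ADDAEEE<GADIAAC@BAGEABGBIEE
@sim:000023
TTGAGCACTAGGCTAGCTGTAGCATTCGGC
+
EFA?BFIBCE>FED?ACBGDEJHDG;BBJC
@sim:000024
CTACAGCTCGTTTGGCAT
+
?CCDFBCBBFEBFEDFCE
@sim:000025
TTCGCTCCACATGAAATAGTCTTAG
+
BB?CFA@CDEFCBEDD=<DEA@CJE
@sim:000026
ATTCTATTTCGGATCTTG
+
AGH@BFCCFD@GDBE?BE
@sim:000027
TTACCATTACACAGTACGATGG
+
HGCFHACHBGEFICDEHDAE>;
@sim:000028
AGACCGATCGCTTCGCCCGCGA
+
ECFCG>@EBDEFDHCCAAICE>
@sim:000030
TTCAAGTTTCAAAAGCTGTC
+
EE@AEJIHBDDADBCEFFFC
@sim:000031
TTACTACAGATACTTCATGGAAATGTCCC
+
F>BIBFB?EEDDFHED?DBEHDDBGFDBC
@sim:000032
CCACTTTTACAGCAAGGAAGTAA
+
FFIEDEEHC?CDD@HDFAI>G@A
@sim:000033
GCAGTCGAAGTAACTGCCA
+
CEICAJHE@B>CD>CC@F?
@sim:000034
GAACAGGTGACTCGCAGTAAAAGGGGC
+
CBCDGAC@DCEBIGA?DGBDDDIGFEG
@sim:000035
AACTACGCACGTCCAGCAACTG
+
IFCBF@B?EIBGDDADDCFD>H
@sim:000036
GGATGGAGAGCTGTCGTTGCACTCCCCTT
+
GEHE@FG@FAD:AH?CFBDHC?GBCCIFG
@sim:000037
ACAAGTCGGGACTTCAAAACGTCCCG
+
FDFBEBBCDFEBAGECBDA?CCEAAA
@sim:000038
CGTAGGTGCGGCAAACCCCTAGCACTCAGA
+
JEFFIDDCCDFEDDDEE@FIABDHDBGD?D
@sim:000039
ATACCCATGAGGTCCCTGCG
+
EBJDDAFCECHABBCEECHA
@sim:000040
TCGGATAAGGGGAAAACAC
+
EADIGDFHF<FGBDAAC@D
@sim:000041
CATGCGTTGGGGAAGAGTCGCC
+
FBBGFBHAEHJCGEEAD?GDAB
@sim:000042
CCAATGTTCTCCTGAAAACC
+
GAICJCD@EBHA>CB??HDG
@sim:000043
CTAGCCATAGTCTCCGATAAAAA
+
EFGAD?HFBDIDEEGEFHCFD?E
@sim:000044
AAACGTCCCTCTATACGCGCCGA
+
DIGHDA>E?JCE>AC@DFF>E?D
@sim:000045
AGTCTATTGGGACTGCCAT
+
@I@CEGDEBE>DFCE@JD@
@sim:000046
GCCAGATAAGCCTATTGTATATTCGGGTAT
+
FC@DCE=JEB@CADGIGCFDEFA=CBDBIF
@sim:000048
CTTTCCACGGTCGCAAAGTGAC
+
AAFEFBFE?EB@FEI?FIC=D>
@sim:000049
TGGCGCGTAAGCTCGAAGGC
+
FCEAFII@FDDADFCJBD@J
@sim:000050
TTAGAAGTGATGCTTCTGCACTGT
+
CCBG@BAFFADCD?FCJDDFD@FE
@sim:000051
TGTTTAAGTCGTCCGACCGTCCGCAATCTA
+
HA?FGJ?BEGC?DFC>EDHGAHH@@FDHCG
@sim:000052
GCGGTCACGCCAAAAGGT
+
EDF=C>DEF@DCBACACD
@sim:000053
TAGCGGACCGCCCCATCTCTGT
+
CGGBJ?FFCCHEGF@DHFBJ@H
@sim:000054
TTGAGCTCCGGGTATCCCTA
+
BJGGAFGIAC@FEEFCFDBG
@sim:000055
CAGCGAGTGCGTCTAGCATAGTCGTTT
+
EG@BADE=CICA>DBDFBDDGJBJECC
@sim:000056
GCAAACCGGTCGCGCAGAAAGA
+
ABBEBGCACJHBDGFB?DDBDF
@sim:000057
AAATTTTGCAGGACCACCGACTCTT
+
BBFB@FAGDACCCDGHEJFBDFBCA
@sim:000058
CTAGGTTTTAGCACCTGAGG
+
ECDEDGJCEJBFDFBCBD@D
@sim:000059
GAATACGACCCATTCCGCAGCGCCAAGT
+
AHBGBEEEHBBEI@GDBECEH=GHDE?F
@sim:000060
CTCTGTCGGTACGGTTCAGTCCCTGAC
+
GBDBBHECEDCD?BAEFBBFJIGA?G?
@sim:000061
TCGATTTATGTCACCGATCATACCAGGTT
+
HBAFECHCFJCCJFECBBDJAFI?FDGCC
@sim:000062
CCGCCTAAATACCTCGGATATACCCAAGAA
+
BAEC=BBJGFDGIACJBJDCD=GEEBFAG>
@sim:000063
TACTAACAATCGCCCAGTACCATATCC
+
>@DIE>DDE>FEBBE?DF@DCE??ACI
@sim:000064
ACGGTGAGTTTACGCCACCAAC
+
CADC>C<B?EJGEBG@EE?EAB
@sim:000065
GGACGGCGGTGATGTAGTTGACCCCTC
+
CGDDHH?ECGEI?FDDEADCD@DEEFD
@sim:000066
AAAAGCGTTATAAATCATCTCGTTAATT
+
FEFDEBCBBBDDABADF@HED?ADCD=F
@sim:000067
TTAGGGGTAAGATGTTGTAATTCGTGGG
+
BJCAGEDB>=EHBFBHCC=CGGGGBDA@
@sim:000068
CCAACAATCTTGTTCGAGTCCGTGAGCTAG
+
DBFDDJDDCCHGCGACCGJDADGGEFFBDJ
@sim:000069
ATACAATGTCATTGGCAG
+
BFGFJCBBCGDAFFGDIE
@sim:000070
CCTGACTCTTCGTCGTCTC
+
IAIBHFFGBBBB?CDIHEB
@sim:000071
GGTAAAACGGCCTCCCAGCAGATTCCAGG
+
GDAEEJCEBJFJBCEEDCBCCI@DDCIEB
@sim:000072
CTACGCGCGACTCTCATAGCTTGGTTGA
+
CFAEDFGF;=F=GB>DAGGHDICCJACG
@sim:000073
ATCGACCCACTTGGCTCTAGGTTCTATGG
+
?FA?FGBCAGGCGCEGG?BDA@FCDIDJG
@sim:000074
AGCCGGCAGATACGCGTA
+
@GIB?>EHICJDFCDEJC
@sim:000075
CTCGAGGAAACGATTAATCCTA
+
BEGBCBFCEEBD?BJDBAHCGD
@sim:000077
ATTCCTTGCTGATAGGGCCTACATGC
+
DAADC>EEJBHBCDDFADC@DEE=IG
@sim:000078
TCGGACGTGTCATCGCCAGGTT
+
CB?GDHACAA@H<CDDDIGDED
@sim:000079
TAAAACTTCTTTGTTATGCAAACTG
+
C?BHCBFCADFDDAE>BGBHCACCD
@sim:000080
GCTCGTTTCACGCTGGAGGTA
+
JFBAFD?C@GAEDB@DGGCBG
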