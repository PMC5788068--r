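@sim:000001
TTCAGTCCTTGTCACGT
+
IFEECEC@FAED@EJJB
@sim:000002
CCCTTCTCTGGACGTAT
+
E@CDCFDAJHA@HFBE>
@sim:000003
ACGTGACTTCGAGCCTA
+
CBFBDD@D?GD=FE?CD
@sim:000004
TCGTAGCCGTAGTGTCA
+
DFECFHGCEA@@EG>BE
@sim:000005
CGGCACGAGGTACGATT
+
DBI@AA;EAEDFFCDCD
@sim:000006
CGCTTTAGATAATGGAG
+
AB?DEDAADDFFJAGJ?
@sim:000007
GACCTGGGATAGTACAT
+
@FHJDGBB?ABIDBBEC
@sim:000008
GTACCAAGCCCGATCCA
+
ACABBHBDGFEBHDFDC
@sim:000009
GAACGCGTTCAGCGCGG
+
@GGHA@HD@BCBADB@E
@sim:000010
AAGCTGGGCAGGCTCGT
+
G@GDIAFADFEBBBADF
@sim:000011
GCACTAGAGCCCTCATC
+
FDCAHHDDEGF@G=FDI
@sim:000012
ATTGACTCGGCAGACGA
+
EAEDDGCCEDEBDBAF@
@sim:000013
CCACCGGCCCCATTAGA
+
ECAFH?CIDDA@CIAFF
@sim:000014
GCCACAAGGTTCGACCG
+
BAFDBCFCJCAHGF>CE
@sim:000015
CCCCAGGGAGCAGGTTC
+
FCHFH>FGH?FFHBEA?
@sim:000016
ATGGCCTAGAGAGGCTT
+
EDAIADBFDDD>@GCBG
@sim:000017
CAGCCCTCCCGATTTAG
+
C@@CECDD?JDEHCB@@
@sim:000018
GCCACGAATTTTGGTCT
+
EH@F?GEAFADACCEAI
@sim:000019
GGACTCCGGAGGTTTCA
+
GAADG@BFBBJEJCDI@
@sim:000020
CGTAACGAACGCCCACC
+
IFIDBFCDGDDCBDEAD
@sim:000021
CGGTTTGCGGCCTCAAG
+
ADGGD@FAAE@EF@CHB
@sim:000022
ATTCACTCTGGCTGTAC
+
HBC@G@IDAG@CCDEFB
@sim:000023
CGAGGGTCGCATAAGAC
+
BHB?DDDDEBF@F?EAG
@sim:000024
TTCGCCGATGGAACCTT
+
DAICDAFFCCGA@AIBD
@sim:000025
GACACTTTAAGCGGCGC
+
BB@JBG@JIIAC@DF@C
@sim:000026
CAGTCTCAACTTGATTG
+
CDCBECECDB@H>FE?I
@sim:000027
CGGAGATTGTGATGAAG
+
AAFGGFJHDAH@ACIJC
@sim:000028
CTACGAAGAGCTGGCAA
+
D?GFHGD@EGGGDC<?G
@sim:000029
AATCTATGAGCGGCGTG
+
EB?GEBHEFD=DFE@BD
@sim:000030
ACGAAGATCCTGTGAAG
+
CICHAFHCI?FBFFJCD
@sim:000031
GTCTTCGATACCGGCCA
+
CFEAHGCECJDAFD>HC
@sim:000032
TGTCATCATGGCCGCTA
+
BFEBIECCBCFDAA?CD
@sim:000033
CGGAATTCGGGCAGGAC
+
DFE=HFEADDBDHHCGE
@sim:000034
CTTGAGTCGCTACAGAG
+
D@EECEGDFCGJDED<>
@sim:000035
GCTGTCGGTAAATCTGC
+
BBFBEF=FHCHE>HGBC
@sim:000036
GAAACCGACTTCGCGCG
+
HCFBDA@FDFCCCDACB
@sim:000037
ATCCGCTTTGCAAGTGC
+
EC?CCJBJGC>EDBCHD
@sim:000038
GCGCCCAAGGTCCTTGA
+
HGCG?FDBDDHE=CD<F
@sim:000039
TTCGTTCCCACTATTCG
+
EJFCHD@EBDFHIECCE
@sim:000040
GTGCCAGTAACTGTAAA
+
I>GEC@B=CE?F@C@FA
@sim:000041
ATATGCGCTTTCTCAAG
+
HBAFEEJBAFIGCJIFD
@sim:000042
CGCCACATTCCTGGAGG
+
GIBFAIHDJFHAC?FHB
@sim:000043
GCCTTCAGAGCCTTTGG
+
D?DCDHDFCABFDDBBG
@sim:000044
CGTCTGTGGAACCCCCT
+
DHDBF@DE@E>BBBE@F
@sim:000045
AGTATCCGGACAACTCG
+
GJBFFGDDDAC@FBJGE
@sim:000046
ATGCGCACGAACTTATA
+
D?IDCDHFCBJBGC@DD
@sim:000047
GGCCAGGCGAGGGCCAA
+
<ACCCC?AIDFECB=EB
@sim:000048
TTTCGCCCCAGACCGCG
+
GCADBAAD?FCBBHEFC
@sim:000049
TTCACGCTCACGTACGT
+
DAFJBGCHEIDEAFCEE
@sim:000050
GGTTTGTGAACAAGTTA
+
CJHECAFGDCEEEH=EJ
@sim:000051
CGGCCTACGCATAATTA
+
FDBCHECDEDEEDCCDD
@sim:000052
CTCTTTGGATCCTGCTC
+
FDICIDEFDEHAJHDDF
@sim:000053
ATGAGCTTGGACGCGAC
+
?@CCDDEJBJECD?I@D
@sim:000054
ACCCCGCACTAAAATAG
+
?HDBFBC@FABDEHEBE
@sim:000055
TGCGGTCACCGGGGTAA
+
GDA?D?DG;@BAA=E?@
@sim:000056
ATTTTCACTGGTCAAGA
+
EDGG?GDFFEE@C?FJ@
@sim:000057
AAAGCCCAAGGTGGTAG
+
?AACFCCFFCEEIHFCD
@sim:000058
AATGGGTGTCCTAGACG
+
IG@BFJBFH@DAFGEHB
@sim:000059
CTATTTCACTCCTTCGT
+
DDCFFDABAGDAAGCAE
@sim:000060
ATTCAATCACGTCATTG
+
HG@JBAHEBCH@IBAEF
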