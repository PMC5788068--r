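@sim:000001
TCCACCATGTTCAGTCCTTGTCACGTACTAATAAGTGTTGGCAGG
+
C?BAJBH9CIFEECEC@FAED@EJJBGDHGBBDEB>HDBCEGB@D
@sim:000002
ATAAGCTCGCTGGCCGCATGCCCTTCTCTGGACGTATATTATATT
+
?>BDHBFECAD?C?JE@FHAE@CDCFDAJHA@HFBE>B@DBDEED
@sim:000003
GGTGATCCCACATGACGTGACTTCGAGCCTAGCTGTACAACTGAC
+
CJCIGFDB>EECEDCBFBDD@D?GD=FE?CDJBFF@@EIHCCFJD
@sim:000004
CCGCTACTTCGATCGATCATGTCGTAGCCGTAGTGTCAGGCAGGC
+
EE?FEEHEDEDBFFEJDEJBCDFECFHGCEA@@EG>BEHE=@EEH
@sim:000005
TATTCATTAAAAGGGGAGACCGCATGCGGCACGAGGTACGATTCG
+
CD@JCIHDGJ@DDEBHB?GBJDDEEBDBI@AA;EAEDFFCDCDJB
@sim:000006
CGTTTATTAACGATTTCATGCGCTTTAGATAATGGAGTTGACCAT
+
EGBEBDCCBDDC@@BH@CDCAB?DEDAADDFFJAGJ?H@FCBFF?
@sim:000007
CTTGGCATGGACCTGGGATAGTACATCTTCTCCAAAATCCTTCTT
+
=@EBHCEDD@FHJDGBB?ABIDBBECD<IHGCBAGBBDDFBEBHG
@sim:000008
CAAGCCACATGGTACCAAGCCCGATCCAGATACCACACGACAACT
+
EEE>EBH=EFAACABBHBDGFEBHDFDCD?FHIDEDCDGCBECCJ
@sim:000009
TCTCATGGAACGCGTTCAGCGCGGGCTACGACGGTCATGCATGCC
+
JBDI@?C@GGHA@HD@BCBADB@EACADBECE>DBIEDHGBDDAD
@sim:000010
TACGTAAACCGGTCATGAAGCTGGGCAGGCTCGTTGGATTTATTG
+
?CCD@@AIFBGFCDIA@G@GDIAFADFEBBBADFDBA@E@FCBA<
@sim:000011
GGACCGCATGGCACTAGAGCCCTCATCGCTAGGGCGGGTGTACAA
+
BEHE<CDGD>FDCAHHDDEGF@G=FDIGHFBGFFD>>ADCEGB@B
@sim:000012
CTTCAAAGTCATGATTGACTCGGCAGACGACGCACCCTGAGCGTC
+
EDAAED?E@C>?HEAEDDGCCEDEBDBAF@HEFCFHJHFBCIEGC
@sim:000013
CTGGCATGCCACCGGCCCCATTAGAGAACGTTTTTGGTGTAAACT
+
AEDBBEFJECAFH?CIDDA@CIAFFCDA@CFD@@EJED@BDEDFD
@sim:000014
GGCATGGCCACAAGGTTCGACCGGAAACTAGCGTGTGCCGTCCCC
+
GIDGFGBAFDBCFCJCAHGF>CEC@H@F>B?D@BHDADG=GEE>D
@sim:000015
GAAATTTCATGCCCCAGGGAGCAGGTTCGTTCTCTTACCCCCTTG
+
DGDDFHCBHDBFCHFH>FGH?FFHBEA?IGGBBBBJBC@HBHED@
@sim:000016
TACCCATCGCCATGATGGCCTAGAGAGGCTTCCCGAACGTGATAG
+
IFD?=?EECCCEC@EDAIADBFDDD>@GCBGDHBCBAF?FFBFEB
@sim:000017
ACTTCTTTGCATGCAGCCCTCCCGATTTAGCAACTGACTACGGTA
+
C?CHGHDIBFGBAC@@CECDD?JDEHCB@@DE?B>EJFDI?DFDC
@sim:000018
CGTGCTCCATGGCCACGAATTTTGGTCTTTCAGGATAGAATTGTA
+
CBDD@A@CHBAEH@F?GEAFADACCEAIFCDACHFBCG>JEGDCD
@sim:000019
ATTAGATATGTTGCCCTATCCATGGGACTCCGGAGGTTTCAATGA
+
BEFFFHDCFC?IEA>CH@HBCIA?GAADG@BFBBJEJCDI@ACHD
@sim:000020
TTCCCATGCGTAACGAACGCCCACCCCCTTGATTGTTATCCTTGG
+
DCGBCA@?IFIDBFCDGDDCBDEADJDB>IGFEIAEIBECDD?DI
@sim:000021
CAGTCACATGCGGTTTGCGGCCTCAAGCCGACCCTGCTGCGCGCC
+
BDCBCFAGCBADGGD@FAAE@EF@CHBE?EFCDBB?GCDFCGIBI
@sim:000022
CCAGCAAATACGCTAGTGCATGATTCACTCTGGCTGTACCATAAA
+
EIEFCBEEG>EBCDCHAAGFEAHBC@G@IDAG@CCDEFB>?GDEC
@sim:000023
GGACCTTTCCAGAGACTCACATGCGAGGGTCGCATAAGACAGTAA
+
E@E@JACDCECBIIGAA?AFCEEBHB?DDDDEBF@F?EAGFDBGE
@sim:000024
TGTACATGTTCGCCGATGGAACCTTGAGGCGCAGCCCGTCAGATG
+
CECEGCDCDAICDAFFCCGA@AIBDJEH=CGBHJEDCJBCBAGCB
@sim:000025
GCTCGTTGTCATGGACACTTTAAGCGGCGCTTCCCAAGATCCGTT
+
ECCJFEBICJADCBB@JBG@JIIAC@DF@C>B@HEBFD@JBDDAG
@sim:000026
ATCATGCAGTCTCAACTTGATTGTACATCCGACCTTCGGCTTAGG
+
CJEDEDCDCBECECDB@H>FE?ID>B@G?BDFABCI@BC?CDACD
@sim:000027
GCGATGAACTAATAAGTCCATGCGGAGATTGTGATGAAGTCCCCG
+
BB>CH?BFAIGEB??FDDJD=DAAFGGFJHDAH@ACIJCC@CCD@
@sim:000028
TCACCACCCGAACCTGACATGCTACGAAGAGCTGGCAAAACTGTA
+
DBI?H>GDADBFEF@DEDDEGD?GFHGD@EGGGDC<?GCEFDCEE
@sim:000029
AACGATACTTACCTTTCATGAATCTATGAGCGGCGTGCCTTCTTC
+
GDCHJHIJGAG?HDFCGDHCEB?GEBHEFD=DFE@BDDFE?H@E@
@sim:000030
CTGTGGTGTCATAGCAGGCATGACGAAGATCCTGTGAAGTAGGAT
+
D=EDAIEBECCGD>EH=GCCA?CICHAFHCI?FBFFJCD@EDHCH
@sim:000031
TCATGGTCTTCGATACCGGCCATACTCGGGGGTTTAGGCATCCAC
+
DFDCBCFEAHGCECJDAFD>HCGEB@DCDEJABCGHGDJEI@FC@
@sim:000032
TTACTCCACGTCGACCCTTGACCCATGTGTCATCATGGCCGCTAA
+
ED?FDD?EEJDEBGD=CEADD?BFC@HBFEBIECCBCFDAA?CDE
@sim:000033
GAGATCATGCGGAATTCGGGCAGGACTCCTTTTTTTTCAAGATGT
+
DEABAD=C?DFE=HFEADDBDHHCGEICDFD?EEGJDAAIBEDG?
@sim:000034
ATTACTTGTAAGTCGCTCATGCTTGAGTCGCTACAGAGATCTGGT
+
CAEBBEFCGGBHHD?ADGFCED@EECEGDFCGJDED<>HFBHBHC
@sim:000035
GGCGTGTTACCCGGGAGCCTCATGGCTGTCGGTAAATCTGCTCTC
+
ICIJBACBECEC@E>FFDDDGGDFBBFBEF=FHCHE>HGBC@DEF
@sim:000036
AGCTCTGCCTGTGAATTGGCGCATGGAAACCGACTTCGCGCGTTA
+
FFDDBDBC@GDF?HHDEBIBJD@E>HCFBDA@FDFCCCDACBHEA
@sim:000037
CTCCTCAATGCAGCCGCTAGCCATGATCCGCTTTGCAAGTGCATT
+
ACD=AGFAC>B@FEIJEGHGHCDDCEC?CCJBJGC>EDBCHDDFF
@sim:000038
CTCGCGTTGTACTGTCATGGCGCCCAAGGTCCTTGACATTGAGTG
+
EA@EHDIH@BJE@BHBG@=HGCG?FDBDDHE=CD<FEGDEAFCCD
@sim:000039
GCATGTTCGTTCCCACTATTCGAGGCCCACGTCATTTGCGCCAGG
+
FADECEJFCHD@EBDFHIECCEH>IFDAJHGFCFBDC@DHFHEEE
@sim:000040
GGTTTGCCCCGCGAAGAGCAACATGGTGCCAGTAACTGTAAAACA
+
FDCBJD@?DDE=EEFDFD?GFDFFDI>GEC@B=CE?F@C@FAEEA
@sim:000041
TTGTCTCATGATATGCGCTTTCTCAAGCAACCGAGAGAAGGGGTT
+
FFGD@GCIB?HBAFEEJBAFIGCJIFDJDCD@@DFCCEECEFFDI
@sim:000042
AATATCGACCCTATGAACCGACCATGCGCCACATTCCTGGAGGAG
+
CHJGE@BEJDCBEIAI@FGEHBHAEDGIBFAIHDJFHAC?FHBG>
@sim:000043
CATGGCCTTCAGAGCCTTTGGGGACAGGGTAGGACCATCGGACAG
+
DBFCD?DCDHDFCABFDDBBGCDAEGGIEEE?D=DCCGEEFCE@E
@sim:000044
TCGCGCCATGCGTCTGTGGAACCCCCTACTCCTACTTACAACGCG
+
DGDCFIEJEADHDBF@DE@E>BBBE@FDFBEHDEBCDEF?HHICH
@sim:000045
ATGGGAAGTATGTACATGAGTATCCGGACAACTCGCTGCATGTAC
+
FFDFG@@AAECIAC=GGBGJBFFGDDDAC@FBJGEFEACDE@GJD
@sim:000046
TTCTCCCGGGCATTCAGAACCGCATGATGCGCACGAACTTATACG
+
CGEAED=FD@BD@BD@DADHCHGDCCD?IDCDHFCBJBGC@DD>D
@sim:000047
CGGTGTGTCGCGCTTCATGGGCCAGGCGAGGGCCAATACCCGCAT
+
FHC>EACBEEDB@FE@DI@<ACCCC?AIDFECB=EBJEBIG@@BD
@sim:000048
TTCTTTAACATCCATGTTTCGCCCCAGACCGCGCGTCCGGATAGG
+
DAHFECE?EF@CDFA>GCADBAAD?FCBBHEFCFDFGDB@DEEBF
@sim:000049
TATTCATGTTCACGCTCACGTACGTCGAGTAACGGTGAACCGCGT
+
BAEG>DD?DAFJBGCHEIDEAFCEEBBHEEFH>?@CCFDBF@ACC
@sim:000050
TAGACCCTGACATGGGTTTGTGAACAAGTTACCTCACCTAGCATA
+
JCGF@JJHE??AJBCJHECAFGDCEEEH=EJ?FEEC=DDHDFGED
@sim:000051
TAACAGTGCTGGTCTAGCTTACAACATGCGGCCTACGCATAATTA
+
EDFAAIB=GADEC@@CC>@IFCECJDHDFDBCHECDEDEEDCCDD
@sim:000052
TTCGTTACAAGGATTGCGGAGATCATGCTCTTTGGATCCTGCTCT
+
C?BB@FFEC@F@CJD<B??@DDBC=@EFDICIDEFDEHAJHDDFA
@sim:000053
AACGTTATGGTGATATCTCATTCATGATGAGCTTGGACGCGACCA
+
DDF@C@EFFEDIGFCGCCGEDFDGDD?@CCDDEJBJECD?I@DBD
@sim:000054
TGTTTAGTTGAGCTCCTCGCATACATGACCCCGCACTAAAATAGA
+
EFADCFDFHGGFEIAGHAIJGFA@JDF?HDBFBC@FABDEHEBEG
@sim:000055
GCACAAACTTCATGTGCGGTCACCGGGGTAAGTAGAGGGATATTG
+
CCFHFGGGBGEGFGGDA?D?DG;@BAA=E?@BFDFF<>FDJC?>H
@sim:000056
TGTCGCTCATGATTTTCACTGGTCAAGAGCCCGAGATCAATGGGA
+
CGBGCGBCAEFEDGG?GDFFEE@C?FJ@?@DIFAAEEDH=BFACJ
@sim:000057
GGAAGGACAGTACACGATAAGGGACATGAAAGCCCAAGGTGGTAG
+
EIDDGDE@BFDCHEBEEJAFEBID@HGB?AACFCCFFCEEIHFCD
@sim:000058
CCCGTACAGCTTTTACTGTCATGAATGGGTGTCCTAGACGGAGCA
+
BBE@HIDGECCGGBBEBCGBDEGIG@BFJBFH@DAFGEHB@ACD?
@sim:000059
TGGGTACCTCATGCTATTTCACTCCTTCGTAGAATCCCACCTTCG
+
>ADC<DDAFGBDEDDCFFDABAGDAAGCAECG@GHBC@FDEAFAD
@sim:000060
CACCCCTGTGAACCAAATTCCATGATTCAATCACGTCATTGGTAT
+
EGCFA?FDADAD=DEDHIED?HGHHG@JBAHEBCH@IBAEFBCCF
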