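@sim000001
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAATGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
MMLLLLLLLKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBBAAAAAA@@@@@@??????>>>>>>=====
@sim000002
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
RRRRRQQQQQQPPPPPPOOOOOONNNNNNNMMMMMMLLLLLLKKKKKKJJJJJJIIIIIIIHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCCBB
@sim000003
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
NNNNMMMMMMMLLLLLLKKKKKKJJJJJJIIIIIIHHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCCBBBBBBAAAAAA@@@@@@??????>>>
@sim000004
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
FFFFEEEEEEEDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@@??????>>>>>>======<<<<<<;;;;;;;::::::999999888888777777666
@sim000005
TTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCATGACAGTGGCTACCT
+
IIHHHHHHGGGGGGFFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBAAAAAAA@@@@@@??????>>>>>>======<<<<<<;;;;;;;::::::99999
@sim000006
GAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGG
+
IIIIIHHHHHHGGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBBAAAAAA@@@@@@??????>>>>>>=======<<<<<<;;;;;;::::::99
@sim000007
TTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCATGACAGTGGCGACCT
+
IIIIIHHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCCBBBBBBAAAAAA@@@@@@??????>>>>>>>======<<<<<<;;;;;;::::::99
@sim000008
TTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTACTTCTTGACAGGGGCGACCT
+
????>>>>>>>======<<<<<<;;;;;;::::::99999998888887777776666665555554444443333333222222111111000000///
@sim000009
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
MMMMMMLLLLLLKKKKKKJJJJJJIIIIIIHHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBBAAAAAA@@@@@@??????>>>>>>==
@sim000010
GAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGG
+
MMLLLLLLLKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBBAAAAAA@@@@@@??????>>>>>>=====
@sim000011
CCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATCTGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGGAGG
+
ONNNNNNMMMMMMLLLLLLKKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGFFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBAAAAAAA@@@@@@??????
@sim000012
GAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGG
+
IIIIIHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@??????>>>>>>>======<<<<<<;;;;;;::::::999
@sim000013
CCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATCTGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGGAGG
+
RQQQQQQPPPPPPOOOOOOONNNNNNMMMMMMLLLLLLKKKKKKJJJJJJIIIIIIIHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDDCCCCCCBBBBBB
@sim000014
GAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGG
+
ONNNNNNMMMMMMMLLLLLLKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBBAAAAAA@@@@@@??????
@sim000015
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
BBAAAAAAA@@@@@@??????>>>>>>======<<<<<<<;;;;;;::::::999999888888777777766666655555544444433333322222
@sim000016
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
MMMLLLLLLKKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGFFFFFFEEEEEEEDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@@??????>>>>>>====
@sim000017
TTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCATGACAGTGGCGACCT
+
GFFFFFFEEEEEEEDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@@??????>>>>>>======<<<<<<;;;;;;;::::::999999888888777777
@sim000018
GAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGG
+
PPOOOOOONNNNNNMMMMMMLLLLLLKKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGFFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@
@sim000019
TTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCAAGACAGTGGCGACCT
+
LLKKKKKKJJJJJJJIIIIIIHHHHHHGGGGGGFFFFFFEEEEEEEDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@@??????>>>>>>======<<<<<
@sim000020
TTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCATGACAGTGGCGACCT
+
^^^]]]]]]]\\\\\\[[[[[[ZZZZZZYYYYYYXXXXXXXWWWWWWVVVVVVUUUUUUTTTTTTSSSSSSRRRRRRRQQQQQQPPPPPPOOOOOONNNN
@sim000021
CCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATCTGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGGGGG
+
AAAA@@@@@@???????>>>>>>======<<<<<<;;;;;;::::::99999998888887777776666665555554444444333333222222111
@sim000022
CCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATCTGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGGAGG
+
AAAA@@@@@@???????>>>>>>======<<<<<<;;;;;;::::::99999998888887777776666665555554444444333333222222111
@sim000023
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
OOOOOONNNNNNMMMMMMLLLLLLLKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGFFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBAAAAAAA@@@@@@?
@sim000024
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
NNMMMMMMLLLLLLKKKKKKKJJJJJJIIIIIIHHHHHHGGGGGGFFFFFFEEEEEEEDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@@??????>>>>>
@sim000025
CCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATCTGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGGAGG
+
FFEEEEEEDDDDDDCCCCCCCBBBBBBAAAAAA@@@@@@??????>>>>>>>======<<<<<<;;;;;;::::::999999988888877777766666
@sim000026
GAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGG
+
HHHHHHGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCCBBBBBBAAAAAA@@@@@@??????>>>>>>=======<<<<<<;;;;;;::::::99999988
@sim000027
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
GGFFFFFFEEEEEEDDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@??????>>>>>>>======<<<<<<;;;;;;::::::999999988888877777
@sim000028
CCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATCTGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGAAGG
+
CCCCCBBBBBBAAAAAA@@@@@@@??????>>>>>>======<<<<<<;;;;;;;::::::999999888888777777666666655555544444433
@sim000029
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
LLLLLLKKKKKKJJJJJJIIIIIIHHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDCCCCCCBBBBBBBAAAAAA@@@@@@??????>>>>>>=======<
@sim000030
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACAC
+
MMMMMMLLLLLLKKKKKKJJJJJJIIIIIIIHHHHHHGGGGGGFFFFFFEEEEEEDDDDDDDCCCCCCBBBBBBAAAAAA@@@@@@???????>>>>>>=
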