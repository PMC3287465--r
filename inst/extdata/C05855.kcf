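ENTRY       C05855   Compound
ATOM        22
            1   C8y  C    0.0000    0.0000
            2   C8x  C    1.0000    0.5000
            3   C8x  C    2.0000    0.0000
            4   C8y  C    2.0000   -1.0000
            5   C8x  C    1.0000   -1.5000
            6   C8x  C    0.0000   -1.0000
            7   C2b  C   -1.0000    0.5000
            8   O2a  O    3.0000   -1.5000
            9   C2b  C   -2.0000    0.0000
            10  C1y  C    4.0000   -1.0000
            11  C1b  C   -3.0000    0.5000
            12  C1y  C    5.0000   -1.5000
            13  O2x  O    4.0000    0.0000
            14  O1a  O   -4.0000    0.0000
            15  O1a  O    5.0000   -2.5000
            16  C1y  C    6.0000   -1.0000
            17  C1y  C    5.0000    0.5000
            18  O1a  O    7.0000   -1.5000
            19  C1y  C    6.0000    0.0000
            20  C1b  C    5.0000    1.5000
            21  O1a  O    7.0000    0.5000
            22  O1a  O    4.0000    2.0000
BOND        23
            1    1   2 2
            2    2   3 1
            3    3   4 2
            4    4   5 1
            5    5   6 2
            6    6   1 1
            7    1   7 1
            8    7   9 2
            9    9  11 1
            10  11  14 1
            11   4   8 1
            12   8  10 1
            13  10  12 1
            14  12  16 1
            15  16  19 1
            16  19  17 1
            17  17  13 1
            18  13  10 1
            19  12  15 1
            20  16  18 1
            21  19  21 1
            22  17  20 1
            23  20  22 1
///
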