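# Built-in molecule connection tables (MDL V2000).
# Kept as plain text so that every fixture used in examples and
# tests parses through the ordinary molfile reader.

.BUILTIN_MOLBLOCKS <- c(

ethyl_acetate = "
  molgrep

  6  5  0  0  0  0  0  0  0  0999 V2000
    2.5981   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4641   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

caffeine = "
  molgrep

 14 15  0  0  0  0  0  0  0  0999 V2000
   -2.1261   -2.7601    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -1.8090    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4049   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -0.1910    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -3.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  6  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5 13  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
  7  8  2  0  0  0  0
  7  9  1  0  0  0  0
  9 10  1  0  0  0  0
  9 11  1  0  0  0  0
 11 12  2  0  0  0  0
 11 13  1  0  0  0  0
 13 14  1  0  0  0  0
M  END
",

theophylline = "
  molgrep

 13 14  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6831   -0.3090    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2709    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6831    1.3090    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    2.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2 12  1  0  0  0  0
  2  3  1  0  0  0  0
  3  7  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
  7  8  1  0  0  0  0
  8  9  2  0  0  0  0
  8 10  1  0  0  0  0
 10 11  1  0  0  0  0
 10 12  1  0  0  0  0
 12 13  2  0  0  0  0
M  END
",

ellipticine = "
  molgrep

 19 22  0  0  0  0  0  0  0  0999 V2000
    2.5058   -2.4476    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5060   -1.4476    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3411   -0.9656    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1767   -1.4482    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0124   -0.9659    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0126   -0.0010    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    4.1771    0.4816    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3413   -0.0007    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5063    0.4817    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5065    1.4817    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6707   -0.0003    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6705   -0.9652    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8353   -1.4473    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0002   -0.9649    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8359   -1.4469    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6709   -0.9646    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6707    0.0003    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8355    0.4824    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2 12  2  0  0  0  0
  2  3  1  0  0  0  0
  3  8  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
  8  9  1  0  0  0  0
  9 10  1  0  0  0  0
  9 11  2  0  0  0  0
 11 19  1  0  0  0  0
 11 12  1  0  0  0  0
 12 13  1  0  0  0  0
 13 14  1  0  0  0  0
 14 19  2  0  0  0  0
 14 15  1  0  0  0  0
 15 16  2  0  0  0  0
 16 17  1  0  0  0  0
 17 18  2  0  0  0  0
 18 19  1  0  0  0  0
M  END
",

sulfanilamide = "
  molgrep

 11 11  0  0  0  0  0  0  0  0999 V2000
   -4.0000   -1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0000   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5000   -0.1340    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5000   -0.1340    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0000   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5000   -1.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5000   -1.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -1.0000    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.0000   -1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  7  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  5  8  1  0  0  0  0
  6  7  1  0  0  0  0
  8  9  1  0  0  0  0
  8 10  2  0  0  0  0
  8 11  2  0  0  0  0
M  END
",

diazepam = "
  molgrep

 20 22  0  0  0  0  0  0  0  0999 V2000
    4.8764    0.7370    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.8792    0.6623    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.5139   -0.2686    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.2469   -0.9487    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.0244   -1.9237    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0688   -2.2184    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8463   -3.1933    0.0000 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    2.3358   -1.5382    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5583   -0.5633    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6573    0.9972    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.3904    1.6774    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3792    1.5283    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9425    2.3546    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2 13  1  0  0  0  0
  2  3  1  0  0  0  0
  3  9  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  6  7  1  0  0  0  0
  6  8  2  0  0  0  0
  8  9  1  0  0  0  0
  9 10  1  0  0  0  0
 10 11  2  0  0  0  0
 10 15  1  0  0  0  0
 11 12  1  0  0  0  0
 12 13  1  0  0  0  0
 13 14  2  0  0  0  0
 15 20  2  0  0  0  0
 15 16  1  0  0  0  0
 16 17  2  0  0  0  0
 17 18  1  0  0  0  0
 18 19  2  0  0  0  0
 19 20  1  0  0  0  0
M  END
",

nag_glycoside = "
  molgrep

 16 16  0  0  1  0  0  0  0  0999 V2000
    2.5981   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
    0.0000   -3.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -3.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
   -1.7321   -2.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    2.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3 12  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
  5  8  1  0  0  0  0
  6  7  1  0  0  0  0
  8  9  1  0  0  0  0
  8 10  1  0  0  0  0
 10 11  1  0  0  0  0
 10 12  1  0  0  0  0
 12 13  1  0  0  0  0
 13 14  1  0  0  0  0
 14 15  1  0  0  0  0
 14 16  2  0  0  0  0
M  END
",

benzene = "
  molgrep

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  6  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

toluene = "
  molgrep

  7  7  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  7  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
M  END
",

furan = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

pyridine = "
  molgrep

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  6  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

pyridone_2 = "
  molgrep

  7  7  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  2  7  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
M  END
",

pyridone_4 = "
  molgrep

  7  7  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  2  7  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
M  END
",

tropylium = "
  molgrep

  7  7  0  0  0  0  0  0  0  0999 V2000
   -0.6235   -0.7818    0.0000 C   0  3  0  0  0  0  0  0  0  0  0  0
   -1.6235   -0.7818    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2470   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0245    0.9749    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1235    1.4088    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2225    0.9749    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  7  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
M  CHG  1   1   1
M  END
",

cyclopentadienide = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  5  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  5  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
M  CHG  1   1  -1
M  END
",

cyclohexane = "
  molgrep

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  6  1  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

cyclooctatetraene = "
  molgrep

  8  8  0  0  0  0  0  0  0  0999 V2000
    0.7071   -0.7071    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7071   -1.7071    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.4142    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0000   -2.4142    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7071   -1.7071    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7071   -0.7071    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  8  1  0  0  0  0
  1  2  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
  7  8  2  0  0  0  0
M  END
",

naphthalene = "
  molgrep

 10 11  0  0  0  0  0  0  0  0999 V2000
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1 10  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  9  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
  7  8  2  0  0  0  0
  8  9  1  0  0  0  0
  9 10  1  0  0  0  0
M  END
",

anthracene = "
  molgrep

 14 16  0  0  0  0  0  0  0  0999 V2000
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4641   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3301   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3301   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4641   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1 14  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4 13  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6 11  1  0  0  0  0
  6  7  1  0  0  0  0
  7  8  2  0  0  0  0
  8  9  1  0  0  0  0
  9 10  2  0  0  0  0
 10 11  1  0  0  0  0
 11 12  2  0  0  0  0
 12 13  1  0  0  0  0
 13 14  1  0  0  0  0
M  END
",

quinoline = "
  molgrep

 10 11  0  0  0  0  0  0  0  0999 V2000
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -2.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1 10  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  9  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
  7  8  2  0  0  0  0
  8  9  1  0  0  0  0
  9 10  1  0  0  0  0
M  END
",

isoquinoline = "
  molgrep

 10 11  0  0  0  0  0  0  0  0999 V2000
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4641    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4641    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1 10  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  8  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
  8  9  2  0  0  0  0
  9 10  1  0  0  0  0
M  END
",

phenylhydrazine = "
  molgrep

  8  8  0  0  0  0  0  0  0  0999 V2000
    1.7321    2.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    1.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  8  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
M  END
",

phenol = "
  molgrep

  7  7  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  7  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
M  END
",

tyrosine = "
  molgrep

 13 13  0  0  1  0  0  0  0  0999 V2000
   -1.7321   -3.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -2.0000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    2.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981   -0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4641   -2.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  2 11  1  0  0  0  0
  3  4  1  0  0  0  0
  4 10  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
  7  8  1  0  0  0  0
  7  9  2  0  0  0  0
  9 10  1  0  0  0  0
 11 12  1  0  0  0  0
 11 13  2  0  0  0  0
M  END
",

propane = "
  molgrep

  3  2  0  0  0  0  0  0  0  0999 V2000
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
M  END
",

ethanol = "
  molgrep

  3  2  0  0  0  0  0  0  0  0999 V2000
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
M  END
",

ethane = "
  molgrep

  2  1  0  0  0  0  0  0  0  0999 V2000
    1.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
",

methane = "
  molgrep

  1  0  0  0  0  0  0  0  0  0999 V2000
    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
",

hcn = "
  molgrep

  2  1  0  0  0  0  0  0  0  0999 V2000
    1.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  3  0  0  0  0
M  END
",

cubane = "
  molgrep

  8 12  0  0  1  0  0  0  0  0999 V2000
    1.1476   -0.0000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
   -0.7032   -0.4052    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
    0.4444   -0.4052    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
    0.4444   -1.5535    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
   -0.7032   -1.5535    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
    0.0000   -1.1474    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
    1.1476   -1.1474    0.0000 C   0  0  3  0  0  0  0  0  0  0  0  0
  1  4  1  0  0  0  0
  1  8  1  0  0  0  0
  1  2  1  0  0  0  0
  2  7  1  0  0  0  0
  2  3  1  0  0  0  0
  3  6  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  8  1  0  0  0  0
  5  6  1  0  0  0  0
  6  7  1  0  0  0  0
  7  8  1  0  0  0  0
M  END
",

pyrrole = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

thiophene = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

pyrimidine = "
  molgrep

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  6  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

pyrazine = "
  molgrep

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  6  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

imidazole = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  1  0  0  0  0
  1  2  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
M  END
",

pyrazole = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

oxazole = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  1  0  0  0  0
  1  2  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

thiazole = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  1  0  0  0  0
  1  2  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

indole = "
  molgrep

  9 10  0  0  0  0  0  0  0  0999 V2000
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -1.8090    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4049   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -0.1910    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  9  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  8  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
  8  9  1  0  0  0  0
M  END
",

benzofuran = "
  molgrep

  9 10  0  0  0  0  0  0  0  0999 V2000
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -1.8090    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4049   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -0.1910    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  9  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  8  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
  8  9  1  0  0  0  0
M  END
",

purine = "
  molgrep

  9 10  0  0  0  0  0  0  0  0999 V2000
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -1.8090    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4049   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8171   -0.1910    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  9  2  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  8  2  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
  8  9  1  0  0  0  0
M  END
",

piperidine = "
  molgrep

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  6  1  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

tetrahydrofuran = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  1  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

morpholine = "
  molgrep

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  6  1  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

cyclopentane = "
  molgrep

  5  5  0  0  0  0  0  0  0  0999 V2000
   -0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6180   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  5  1  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

cyclopropane = "
  molgrep

  3  3  0  0  0  0  0  0  0  0999 V2000
    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5000   -0.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  3  1  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
M  END
",

methylamine = "
  molgrep

  2  1  0  0  0  0  0  0  0  0999 V2000
    1.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
",

acetaldehyde = "
  molgrep

  3  2  0  0  0  0  0  0  0  0999 V2000
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
M  END
",

methanimine_n_methyl = "
  molgrep

  4  3  0  0  0  0  0  0  0  0999 V2000
    2.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5000    0.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5000    0.8660    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  3  0  0  0
  3  4  1  0  0  0  0
M  END
",

water = "
  molgrep

  1  0  0  0  0  0  0  0  0  0999 V2000
    1.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
M  END
",

methyl_acetate = "
  molgrep

  5  4  0  0  0  0  0  0  0  0999 V2000
    1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  3  5  2  0  0  0  0
M  END
",

hydrazine = "
  molgrep

  2  1  0  0  0  0  0  0  0  0999 V2000
    1.0000   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
",

acetohydrazide = "
  molgrep

  5  4  0  0  0  0  0  0  0  0999 V2000
    1.7321   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981    0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
  4  5  1  0  0  0  0
M  END
",

methanol = "
  molgrep

  2  1  0  0  0  0  0  0  0  0999 V2000
    1.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
",

methyl_isocyanate = "
  molgrep

  4  3  0  0  0  0  0  0  0  0999 V2000
    2.5981    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  2  0  0  0  0
M  END
",

dimethylurea = "
  molgrep

  6  5  0  0  0  0  0  0  0  0999 V2000
    2.5981   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981   -0.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321    1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  3  5  1  0  0  0  0
  5  6  1  0  0  0  0
M  END
",

chfclbr_r_2d = "
  molgrep

  4  3  0  0  1  0  0  0  0  0999 V2000
   -0.0000    1.0000    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
    0.8660    1.5000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 Cl  0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 Br  0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  1  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
M  END
",

chfclbr_s_2d = "
  molgrep

  4  3  0  0  1  0  0  0  0  0999 V2000
   -0.0000    1.0000    0.0000 C   0  0  1  0  0  0  0  0  0  0  0  0
    0.8660    1.5000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 Cl  0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 Br  0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  6  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
M  END
",

chfclbr_r_3d = "
  molgrep

  5  4  0  0  1  0  0  0  0  0999 V2000
    1.0482   -0.0396   -0.0739 C   0  0  2  0  0  0  0  0  0  0  0  0
    0.5904   -0.6539   -1.1939 F   0  0  0  0  0  0  0  0  0  0  0  0
    0.4522    1.6185   -0.0160 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    2.9850   -0.0561   -0.0606 Br  0  0  0  0  0  0  0  0  0  0  0  0
    0.6993   -0.5905    0.8030 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  4  1  0  0  0  0
  1  3  1  0  0  0  0
  1  2  1  0  0  0  0
  1  5  1  1  0  0  0
M  END
",

chfclbr_s_3d = "
  molgrep

  5  4  0  0  1  0  0  0  0  0999 V2000
    1.0306    0.0864    0.0524 C   0  0  1  0  0  0  0  0  0  0  0  0
    0.5728    0.5039    1.2597 F   0  0  0  0  0  0  0  0  0  0  0  0
    0.4346    1.1568   -1.2152 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    2.9674    0.0655    0.0556 Br  0  0  0  0  0  0  0  0  0  0  0  0
    0.6818   -0.9333   -0.1282 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  6  0  0  0
M  END
",

e_2_butene = "
  molgrep

  4  3  0  0  0  0  0  0  0  0999 V2000
    2.5981   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
M  END
",

z_2_butene = "
  molgrep

  4  3  0  0  0  0  0  0  0  0999 V2000
    2.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5000    0.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5000    0.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
M  END
"
)
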