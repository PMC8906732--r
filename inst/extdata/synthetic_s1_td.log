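 Entering Link 1
 Excitation energies and oscillator strengths:
 Excited State   1:      Singlet-A      2.2400 eV   553.50 nm  f=0.1280  <S**2>=0.000
 Excited State   2:      Singlet-A      2.9100 eV   426.06 nm  f=0.0060  <S**2>=0.000
 Excited State   3:      Singlet-A      3.3200 eV   373.45 nm  f=0.0510  <S**2>=0.000

 Excitation energies and oscillator strengths:
 Excited State   1:      Singlet-A      2.1900 eV   566.14 nm  f=0.1280  <S**2>=0.000
 Excited State   2:      Singlet-A      2.8600 eV   433.51 nm  f=0.0060  <S**2>=0.000
 Excited State   3:      Singlet-A      3.2700 eV   379.16 nm  f=0.0510  <S**2>=0.000

 Excitation energies and oscillator strengths:
 Excited State   1:      Singlet-A      2.1400 eV   579.37 nm  f=0.1280  <S**2>=0.000
 Excited State   2:      Singlet-A      2.8100 eV   441.22 nm  f=0.0060  <S**2>=0.000
 Excited State   3:      Singlet-A      3.2200 eV   385.04 nm  f=0.0510  <S**2>=0.000

 Normal termination.
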