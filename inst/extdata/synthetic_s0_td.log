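 Entering Link 1
 Excitation energies and oscillator strengths:
 Excited State   1:      Singlet-A      2.9200 eV   424.60 nm  f=0.1920  <S**2>=0.000
 Excited State   2:      Singlet-A      3.4600 eV   358.34 nm  f=0.0130  <S**2>=0.000
 Excited State   3:      Singlet-A      4.0000 eV   309.96 nm  f=0.2840  <S**2>=0.000

 Excitation energies and oscillator strengths:
 Excited State   1:      Singlet-A      2.8700 eV   432.00 nm  f=0.1920  <S**2>=0.000
 Excited State   2:      Singlet-A      3.4100 eV   363.59 nm  f=0.0130  <S**2>=0.000
 Excited State   3:      Singlet-A      3.9500 eV   313.88 nm  f=0.2840  <S**2>=0.000

 Normal termination.
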