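>MINAR2_synthetic_190aa three engineered CRAC/CARC motifs; NOT the real protein
APAQTGANETQPTGSQQTPPTGNSANDNTTVAYAKDGPTGNGSNEAPGDDGTSDPGEDNPAAETQTQSPNPDGGNKAFAL
AGPNENPTQTEGPDSDAQQPQNEDAPQENAQQSADNPADALAAYAARGGDDDDTGEQAGNNGQGGQDPAAPSAPSDTATT
TAQAATAAAGNSPASPNDEEQQQSGPQTQD
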