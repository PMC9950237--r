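family,baseline,model,aic,bic
EAR,variable,BEIR,57440,57651
EAR,variable,GrantL,57439,57611
EAR,variable,GrantLQ,57436,57619
EAR,variable,INWORKSL,57417,57701
EAR,variable,INWORKSLQ,57416,57711
EAR,variable,OzasaL,57410,57674
EAR,variable,OzasaLQ,57409,57683
EAR,variable,PrestonL,57417,57620
EAR,variable,PrestonLQ,57414,57627
EAR,variable,UNSCEARL,57381,57655
EAR,variable,UNSCEARLQ,57383,57667
ERR,variable,BEIR,57671,62775
ERR,variable,GrantL,57438,57610
ERR,variable,GrantLQ,57436,57619
ERR,variable,INWORKSL,57751,63363
ERR,variable,INWORKSLQ,57751,62767
ERR,variable,OzasaL,57672,62787
ERR,variable,OzasaLQ,57672,62797
ERR,variable,PrestonL,57417,57620
ERR,variable,PrestonLQ,57415,57628
ERR,variable,UNSCEARL,57370,57644
ERR,variable,UNSCEARLQ,57372,57656
EAR,constant,BEIR,57413,57605
EAR,constant,GrantL,57417,57620
EAR,constant,GrantLQ,57415,57627
EAR,constant,INWORKSL,57426,57648
EAR,constant,INWORKSLQ,57422,57701
EAR,constant,UNSCEARL,57422,57614
EAR,constant,UNSCEARLQ,57423,57626
ERR,constant,BEIR,57413,57605
ERR,constant,GrantL,57417,57620
ERR,constant,GrantLQ,57415,57628
ERR,constant,INWORKSL,57421,57644
ERR,constant,INWORKSLQ,57420,57653
ERR,constant,UNSCEARL,57418,57611
ERR,constant,UNSCEARLQ,57420,57623
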