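variant,meso-DAP,2-APA,alpha-aminoadipic acid,D-glutamate,D-ornithine,D-norleucine,D-phenylalanine
WT,675 (70),14.7 (1.5),n.a.,n.a.,26.6 (4.3),n.a.,n.a.
E315T,26.3 (0.9),482 (36),3.2 (0.2),n.a.,n.a.,n.a.,n.a.
E315F,36.0 (6.5),21 (1),3.2 (0.7),n.a.,n.a.,4.2 (0.2),4.1 (0.1)
E315P,22.6 (3.4),9.1 (1.5),7.3 (0.4),n.a.,n.a.,n.a.,n.a.
E315M,111 (21),62 (3),13 (2),n.a.,n.a.,n.a.,n.a.
E315L,32.7 (3.9),36.5 (0.7),12.4 (0.8),n.a.,n.a.,13.8 (0.4),13.3 (0.9)
E315Q,82 (11),41 (4),8.1 (0.6),5.9 (0.1),n.a.,n.a.,n.a.
E315N,42 (1),41.6 (5),32.3 (2.6),n.a.,n.a.,n.a.,n.a.
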