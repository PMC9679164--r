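390 0.312619599714319
395 0.39289708781174
400 0.480446685814991
405 0.572192815594017
410 0.664321795961378
415 0.752564467098559
420 0.832551869725454
425 0.900199012346473
430 0.952066937955494
435 0.985657095588833
440 0.999603334036677
445 0.993743106724913
450 0.969067391990242
455 0.927565113553657
460 0.871989931000715
465 0.8055837314308
470 0.731791795670273
475 0.654000292860153
480 0.575319023490723
485 0.498422995033506
490 0.425457168801175
495 0.358000863809368
500 0.297082624272982
505 0.243233110588721
510 0.196562588908893
515 0.156850415856768
520 0.123635953113654
525 0.0963030082678749
530 0.0741526775124818
535 0.0564619924120341
540 0.0425278241445796
545 0.031696983302303
550 0.0233843817779223
555 0.0170815717101071
560 0.0123580542679549
565 0.00885757466560138
570 0.00629129506363102
575 0.00442934945905089
580 0.00309189616900473
585 0.00214043343558109
590 0.00146985255484504
595 0.00100147719728185
600 0.000677174262658108
605 0.000454512333851777
610 0.000302877887523856
615 0.000200426019387593
620 0.000131731765944437
625 8.60120729305303e-05
630 5.58008581784613e-05
635 3.59759722378013e-05
640 2.30541801127238e-05
645 1.46867371707777e-05
650 9.30272743296407e-06
655 5.85967231520044e-06
660 3.67097241103371e-06
665 2.28769648916555e-06
670 1.4183650867958e-06
675 8.75005985391215e-07
680 5.37188418341302e-07
685 3.28240710641402e-07
690 1.99647718673215e-07
695 1.20891758612375e-07
700 7.28856904306654e-08
705 4.37574896235198e-08
710 2.61623624468793e-08
715 1.55798922286718e-08
720 9.24191630508117e-09
725 5.46154564417108e-09
730 3.21565662916357e-09
735 1.88654743732697e-09
740 1.10294022503174e-09
745 6.42633694378299e-10
750 3.73200541863777e-10
755 2.16036541114713e-10
760 1.2466835516205e-10
765 7.17242798098963e-11
770 4.11427231970189e-11
775 2.35326980413009e-11
780 1.34225901807165e-11
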