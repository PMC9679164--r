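390 0.00499549185625788
395 0.00825357933323227
400 0.0132225674801147
405 0.0205618786714499
410 0.0310689938337471
415 0.0456597624885104
420 0.0653263918230298
425 0.0910713048514963
430 0.123818435119681
435 0.164307531550795
440 0.212981029163142
445 0.269876223067885
450 0.334537124462155
455 0.40595994702695
460 0.482583487798137
465 0.562330964547719
470 0.642703785692653
475 0.720921179216411
480 0.79409362649193
485 0.859413581245022
490 0.914344685843115
495 0.956790928305943
500 0.985229797986663
505 0.998798008250428
510 0.997324013485398
515 0.981307497190912
520 0.951851430556826
525 0.910556546904724
530 0.85939074401243
535 0.800546885207811
540 0.736301844157421
545 0.668887742505545
550 0.60038359198949
555 0.532632432978965
560 0.46718598079001
565 0.405276082892503
570 0.347810173742193
575 0.295386491438355
580 0.248324090064874
585 0.206702562830827
590 0.170406753801721
595 0.139172428693821
600 0.112629748913082
605 0.090342318127737
610 0.0718404466520849
615 0.0566480377361259
620 0.044303104312753
625 0.034372363668124
630 0.0264606392157572
635 0.0202159441652701
640 0.0153311591012538
645 0.0115431737344868
650 0.008630269920671
655 0.00640840200486578
660 0.00472690014660909
665 0.00346399583543685
670 0.0025224549156945
675 0.00182550675903862
680 0.00131318038320409
685 0.000939098819515093
690 0.000667740044918057
695 0.000472143782659121
700 0.000332025678547865
705 0.00023225111227723
710 0.000161617830649269
715 0.000111897701777473
720 7.70916052903764e-05
725 5.28565990469131e-05
730 3.60701824592171e-05
735 2.45021340548533e-05
740 1.65696787537384e-05
745 1.11564434649276e-05
750 7.47970784447551e-06
755 4.99384649425257e-06
760 3.32063231393613e-06
765 2.19929603314101e-06
770 1.45099217310575e-06
775 9.53685244693388e-07
780 6.24514891428374e-07
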