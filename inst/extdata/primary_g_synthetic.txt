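390 1.64619380271069e-09
395 5.75728400702717e-09
400 1.934561612473e-08
405 6.24562203531775e-08
410 1.93730077462483e-07
415 5.77359912346592e-07
420 1.65319628742753e-06
425 4.54810452368266e-06
430 1.2021666434369e-05
435 3.05300229346785e-05
440 7.44934020193049e-05
445 0.000174637178839779
450 0.000393354231363061
455 0.000851254001310499
460 0.00176995704686281
465 0.00353585550150758
470 0.00678663528497487
475 0.0125153423412237
480 0.0221747727248552
485 0.037748860091299
490 0.0617414360834291
495 0.097023700041287
500 0.146489723462366
505 0.212502824275022
510 0.296176416650267
515 0.396610733289965
520 0.510277797795504
525 0.630778820547428
530 0.749162022824993
535 0.854875016724669
540 0.937254895612678
545 0.987281571590291
550 0.999200319914684
555 0.971610767189123
560 0.90773753548683
565 0.814810262168729
570 0.702717722868398
575 0.582282240201813
580 0.463569017495998
585 0.354587548560899
590 0.260591821012689
595 0.18400359196772
600 0.124830307995833
605 0.0813658196645253
610 0.0509556312701942
615 0.0306598897940075
620 0.0177246314401778
625 0.00984491697639244
630 0.00525381920098538
635 0.00269380658042149
640 0.00132704581365057
645 0.000628107014976498
650 0.000285633796333148
655 0.000124799763133437
660 5.23897288585694e-05
665 2.1130353430442e-05
670 8.1883348155182e-06
675 3.04868563368986e-06
680 1.09058097405398e-06
685 3.74827468817522e-07
690 1.23775053928646e-07
695 3.92701951078442e-08
700 1.197074596224e-08
705 3.505965117042e-09
710 9.86557011941944e-10
715 2.66725787066901e-10
720 6.92844930696904e-11
725 1.72916048671523e-11
730 4.14631967686312e-12
735 9.55253160529781e-13
740 2.11447426878954e-13
745 4.49691363202333e-14
750 9.18871770347992e-15
755 1.80394583259278e-15
760 3.40267364203979e-16
765 6.16659351490994e-17
770 1.07373860390338e-17
775 1.7963048142704e-18
780 2.88728544084692e-19
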