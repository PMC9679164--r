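390 0.000262413573851639
395 0.00049242625847432
400 0.000894561076611018
405 0.00157497661330393
410 0.00269025868044145
415 0.0044628315872843
420 0.00719689960484229
425 0.0112928378780478
430 0.0172572199829791
435 0.0257051478084405
440 0.0373514271554678
445 0.0529875747462804
450 0.0734427445947074
455 0.09952840788516
460 0.131968859320971
465 0.171322071267117
470 0.217897695083583
475 0.271680702827084
480 0.332269902617891
485 0.398840100849868
490 0.470134959895963
495 0.544494755754871
500 0.619919615873528
505 0.694164895214851
510 0.764861672272957
515 0.829652429391971
520 0.886330220905246
525 0.932969248112247
530 0.96803576605135
535 0.99047046052396
540 0.999736516048291
545 0.995831114653809
550 0.979261608823035
555 0.950990692657868
560 0.912357244697576
565 0.864980953209502
570 0.810659314882016
575 0.751265196779673
580 0.688652037862669
585 0.624572164723542
590 0.560611848682544
595 0.498144864936354
600 0.438304616132672
605 0.38197348540347
610 0.329787061847468
615 0.282150254463326
620 0.23926205363341
625 0.201145755727885
630 0.167681761437788
635 0.138640511572743
640 0.113713659048266
645 0.0925421275364329
650 0.0747402255853113
655 0.059915435796642
660 0.0476838628687478
665 0.0376815957603832
670 0.0295724215317214
675 0.0230524318692278
680 0.0178521019750438
685 0.0137364108347273
690 0.0105035268537242
695 0.00798251679547732
700 0.00603045985365374
705 0.00452927097244005
710 0.00338246413346232
715 0.00251202100038793
720 0.00185547499541206
725 0.00136327614352616
730 0.00099646746059452
735 0.00072467826647242
740 0.00052442223501495
745 0.000377676799053277
750 0.000270714300613394
755 0.000193152739618888
760 0.000137194037033459
765 9.70195010081606e-05
770 6.83149729987477e-05
775 4.79014175736055e-05
780 3.34501378777734e-05
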