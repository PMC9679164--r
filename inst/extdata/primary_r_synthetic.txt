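390 1.84668933734545e-33
395 5.38018616002114e-32
400 1.45107676332447e-30
405 3.62303972252429e-29
410 8.37424045460638e-28
415 1.79187364338223e-26
420 3.54943280924343e-25
425 6.50878851546785e-24
430 1.10492038260968e-22
435 1.73640662026193e-21
440 2.52616378092569e-20
445 3.40221064097157e-19
450 4.24180320916541e-18
455 4.89586526458611e-17
460 5.23116021989924e-16
465 5.17435485932625e-15
470 4.73809779628813e-14
475 4.01644158343527e-13
480 3.15187156673273e-12
485 2.28973484564555e-11
490 1.53989637849684e-10
495 9.58710370390841e-10
500 5.52551772036671e-09
505 2.94814031866377e-08
510 1.45617291109133e-07
515 6.65836146985732e-07
520 2.81845699500814e-06
525 1.10444750897763e-05
530 4.00652973929511e-05
535 0.000134549251080339
540 0.000418296106423912
545 0.0012038599948282
550 0.00320743428174772
555 0.00791095973393025
560 0.0180630134197813
565 0.0381804338005358
570 0.0747104127384246
575 0.135335283236613
580 0.226950194886959
585 0.352321954995497
590 0.506335616648101
595 0.673638455344727
600 0.829669047996713
605 0.945959468906765
610 0.99845798025953
615 0.975610980064846
620 0.882496902584595
625 0.738991296280309
630 0.572868681636493
635 0.411112290507187
640 0.273121232801778
645 0.167973236757534
650 0.0956344448325386
655 0.0504055333627536
660 0.0245941439897238
665 0.0111089965382423
670 0.00464523377233289
675 0.00179816666184758
680 0.000644379820568608
685 0.000213768418818092
690 6.56500077276156e-05
695 1.86644691135205e-05
700 4.91231405886109e-06
705 1.19686793300253e-06
710 2.69957850336301e-07
715 5.63683489559872e-08
720 1.089592965924e-08
725 1.94976778601724e-09
730 3.22991515217176e-10
735 4.95323531073229e-11
740 7.03196062084075e-12
745 9.24173525066395e-13
750 1.12439845303018e-13
755 1.26641655490942e-14
760 1.32045176700359e-15
765 1.2745536715638e-16
770 1.13889408651823e-17
775 9.42102531722078e-19
780 7.21444002015973e-20
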