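390 1.693161243613e-05
395 6.97695771959971e-05
400 0.000260748784668827
405 0.00088382630693505
410 0.00271706472932358
415 0.00757567744425994
420 0.0191571718371291
425 0.0439369336234074
430 0.0913937553560472
435 0.172421623893753
440 0.295022656174443
445 0.457833361771614
450 0.644388724825195
455 0.822577562398665
460 0.952344799895176
465 1
470 0.952344799895176
475 0.822577562398665
480 0.644388724825195
485 0.457833361771614
490 0.295022656174443
495 0.172421623893753
500 0.0913937553560472
505 0.0439369336234074
510 0.0191571718371291
515 0.00757567744425994
520 0.00271706472932358
525 0.00088382630693505
530 0.000260748784668827
535 6.97695771959971e-05
540 1.693161243613e-05
545 3.72665317207867e-06
550 7.43923131743503e-07
555 1.34686968880871e-07
560 2.21162517582715e-08
565 3.29371411030608e-09
570 4.44885965012935e-10
575 5.45004313288414e-11
580 6.05535491770821e-12
585 6.10193667760532e-13
590 5.57678907911153e-14
595 4.62263040548371e-15
600 3.47522200360187e-16
605 2.36954174734018e-17
610 1.46532718044024e-18
615 8.21851355409674e-20
620 4.18061693551704e-21
625 1.92874984796392e-22
630 8.07048925515247e-24
635 3.06275496061462e-25
640 1.05417586690387e-26
645 3.29080627727491e-28
650 9.31708363305703e-30
655 2.39246779350731e-31
660 5.57186564892025e-33
665 1.17691094392167e-34
670 2.25462851897053e-36
675 3.91737205076394e-38
680 6.17309661654006e-40
685 8.82266435749468e-42
690 1.14362823843769e-43
695 1.34449258914351e-45
700 1.43357488710561e-47
705 1.38634329364117e-49
710 1.21593292017954e-51
715 9.67245854458505e-54
720 6.97834709366812e-56
725 4.56621846799413e-58
730 2.70987485441522e-60
735 1.45857986279906e-62
740 7.12032178989775e-65
745 3.15251715514503e-67
750 1.26591260833629e-69
755 4.61039803795696e-72
760 1.52286549860989e-74
765 4.56218721317234e-77
770 1.23957579654816e-79
775 3.05465032298705e-82
780 6.82713272539135e-85
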