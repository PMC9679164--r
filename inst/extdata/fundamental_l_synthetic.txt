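390 2.30224234221124e-05
395 4.72049134248895e-05
400 9.35951202481429e-05
405 0.000179656319444601
410 0.000334215945830548
415 0.00060319687041683
420 0.001057233613769
425 0.00180126416498044
430 0.00298590388742122
435 0.00482000303267684
440 0.00758328718961142
445 0.0116374369990018
450 0.0174334690122866
455 0.025512947431932
460 0.0365005072783928
465 0.0510855060945672
470 0.0699914011726818
475 0.0939326608221828
480 0.123560566736195
485 0.159400973997241
490 0.201788727497682
495 0.2508047234209
500 0.306222305276921
505 0.367469614445079
510 0.433613597732093
515 0.503369657225762
520 0.57513858426581
525 0.647069725794231
530 0.717146624899188
535 0.783289003990957
540 0.843463220051645
545 0.895792428620323
550 0.938657740269025
555 0.970782607239941
560 0.991294390588412
565 0.999759294910934
570 0.996189336087618
575 0.981022439372147
580 0.955078895339792
585 0.919499036409865
590 0.875668022594808
595 0.8251340102965
600 0.769525765901588
605 0.710475078769767
610 0.649548265451762
615 0.58818979310372
620 0.527679734382082
625 0.469105526956998
630 0.413347445417143
635 0.361076363469456
640 0.312761816799875
645 0.268688068217819
650 0.228975799783427
655 0.19360716905377
660 0.162452218224466
665 0.135294964672787
670 0.111857882342262
675 0.0918238663337461
680 0.0748551282070389
685 0.0606087768590961
690 0.048749088496889
695 0.0389566558708588
700 0.0309347341493611
705 0.0244131751943921
710 0.0191503724756505
715 0.0149336352751115
720 0.0115783828495277
725 0.00892650556662248
730 0.0068441880753939
735 0.00521943512033288
740 0.00395948792449308
745 0.00298827099964593
750 0.00224396745151405
755 0.00167678604537754
760 0.00124695549172608
765 0.000922960134716152
770 0.000680015720482358
775 0.000498773290775125
780 0.000364232563930286
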