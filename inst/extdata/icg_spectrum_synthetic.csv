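"wavelength_nm","absorbance"
600,0
601,0
602,0
603,0
604,0
605,0
606,0
607,0
608,0
609,0
610,0
611,0
612,0
613,0
614,0
615,0
616,0
617,0
618,0
619,0
620,0
621,0
622,0
623,0
624,0
625,0
626,0
627,1e-06
628,1e-06
629,1e-06
630,1e-06
631,1e-06
632,2e-06
633,2e-06
634,3e-06
635,4e-06
636,5e-06
637,7e-06
638,9e-06
639,1.1e-05
640,1.4e-05
641,1.7e-05
642,2.1e-05
643,2.7e-05
644,3.3e-05
645,4.2e-05
646,5.2e-05
647,6.4e-05
648,7.8e-05
649,9.6e-05
650,0.000118
651,0.000144
652,0.000175
653,0.000212
654,0.000257
655,0.000309
656,0.000372
657,0.000445
658,0.000532
659,0.000633
660,0.000751
661,0.000889
662,0.001048
663,0.001233
664,0.001445
665,0.001689
666,0.001968
667,0.002285
668,0.002646
669,0.003054
670,0.003515
671,0.004032
672,0.004612
673,0.005258
674,0.005977
675,0.006773
676,0.007651
677,0.008616
678,0.009674
679,0.010827
680,0.012081
681,0.013438
682,0.014902
683,0.016475
684,0.018157
685,0.01995
686,0.021852
687,0.023861
688,0.025975
689,0.028189
690,0.030498
691,0.032894
692,0.03537
693,0.037914
694,0.040517
695,0.043165
696,0.045844
697,0.04854
698,0.051237
699,0.053917
700,0.056564
701,0.059158
702,0.061681
703,0.064115
704,0.066441
705,0.06864
706,0.070696
707,0.072591
708,0.07431
709,0.075839
710,0.077165
711,0.078277
712,0.079166
713,0.079825
714,0.080249
715,0.080437
716,0.080389
717,0.080107
718,0.079595
719,0.078862
720,0.077917
721,0.076772
722,0.07544
723,0.073939
724,0.072284
725,0.070496
726,0.068595
727,0.066603
728,0.064541
729,0.062433
730,0.060302
731,0.058173
732,0.056067
733,0.054009
734,0.052021
735,0.050125
736,0.048342
737,0.046694
738,0.045198
739,0.043873
740,0.042736
741,0.041803
742,0.041087
743,0.040601
744,0.040357
745,0.040364
746,0.04063
747,0.041163
748,0.041969
749,0.04305
750,0.044411
751,0.046052
752,0.047972
753,0.050172
754,0.052647
755,0.055394
756,0.058407
757,0.061678
758,0.0652
759,0.068963
760,0.072955
761,0.077164
762,0.081576
763,0.086176
764,0.090946
765,0.09587
766,0.100926
767,0.106096
768,0.111356
769,0.116685
770,0.122057
771,0.127449
772,0.132835
773,0.138187
774,0.143481
775,0.148687
776,0.15378
777,0.158732
778,0.163516
779,0.168105
780,0.172473
781,0.176596
782,0.180449
783,0.184009
784,0.187256
785,0.19017
786,0.192732
787,0.194928
788,0.196743
789,0.198166
790,0.199189
791,0.199804
792,0.200009
793,0.1998
794,0.199181
795,0.198153
796,0.196725
797,0.194903
798,0.192701
799,0.190129
800,0.187206
801,0.183946
802,0.180371
803,0.1765
804,0.172356
805,0.167961
806,0.163341
807,0.15852
808,0.153524
809,0.148378
810,0.143109
811,0.137742
812,0.132303
813,0.126816
814,0.121306
815,0.115796
816,0.110308
817,0.104864
818,0.099482
819,0.094182
820,0.08898
821,0.083892
822,0.078933
823,0.074113
824,0.069445
825,0.064938
826,0.060598
827,0.056434
828,0.052449
829,0.048648
830,0.045033
831,0.041606
832,0.038367
833,0.035317
834,0.032454
835,0.029778
836,0.027288
837,0.024983
838,0.022862
839,0.020925
840,0.019174
841,0.017609
842,0.016236
843,0.015061
844,0.014092
845,0.01334
846,0.012822
847,0.012555
848,0.012563
849,0.012875
850,0.013523
851,0.014547
852,0.015992
853,0.01791
854,0.020357
855,0.023397
856,0.027101
857,0.031542
858,0.036801
859,0.042961
860,0.050108
861,0.058329
862,0.067708
863,0.078328
864,0.090266
865,0.103589
866,0.118353
867,0.134601
868,0.152356
869,0.171623
870,0.192382
871,0.214588
872,0.238164
873,0.263009
874,0.288985
875,0.315926
876,0.343634
877,0.371879
878,0.400406
879,0.428935
880,0.457163
881,0.484773
882,0.511439
883,0.536829
884,0.560613
885,0.582474
886,0.602109
887,0.61924
888,0.633618
889,0.645032
890,0.653309
891,0.658326
892,0.660007
893,0.658324
894,0.653304
895,0.645023
896,0.633606
897,0.619225
898,0.60209
899,0.582449
900,0.560583
901,0.536791
902,0.511393
903,0.484718
904,0.457096
905,0.428855
906,0.400311
907,0.371765
908,0.343497
909,0.315764
910,0.288793
911,0.262781
912,0.237896
913,0.214271
914,0.19201
915,0.171186
916,0.151844
917,0.134002
918,0.117654
919,0.102775
920,0.089321
921,0.077233
922,0.066441
923,0.056867
924,0.048424
925,0.041025
926,0.034579
927,0.028998
928,0.024194
929,0.020083
930,0.016586
931,0.013628
932,0.011141
933,0.009061
934,0.007332
935,0.005903
936,0.004728
937,0.003768
938,0.002987
939,0.002356
940,0.001849
941,0.001444
942,0.001122
943,0.000867
944,0.000666
945,0.00051
946,0.000388
947,0.000294
948,0.000221
949,0.000166
950,0.000124
951,9.2e-05
952,6.8e-05
953,5e-05
954,3.6e-05
955,2.6e-05
956,1.9e-05
957,1.4e-05
958,1e-05
959,7e-06
960,5e-06
961,4e-06
962,2e-06
963,2e-06
964,1e-06
965,1e-06
966,1e-06
967,0
968,0
969,0
970,0
971,0
972,0
973,0
974,0
975,0
976,0
977,0
978,0
979,0
980,0
981,0
982,0
983,0
984,0
985,0
986,0
987,0
988,0
989,0
990,0
991,0
992,0
993,0
994,0
995,0
996,0
997,0
998,0
999,0
1000,0
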