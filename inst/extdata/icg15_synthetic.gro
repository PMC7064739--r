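synthetic rod-dye configuration, 15 ICG molecules (generated fixture)
   45
    1ICG     C1    1   0.860   8.640   2.588
    1ICG     C2    2   0.346   9.287   2.946
    1ICG     C3    3  -0.167   9.933   3.303
    2ICG     C1    4   5.192   2.364   8.818
    2ICG     C2    5   5.192   2.364   9.718
    2ICG     C3    6   5.192   2.364  10.618
    3ICG     C1    7   6.325   9.583   7.964
    3ICG     C2    8   6.325   9.583   8.864
    3ICG     C3    9   6.325   9.583   9.764
    4ICG     C1   10   5.232   7.159   6.506
    4ICG     C2   11   5.232   7.159   7.406
    4ICG     C3   12   5.232   7.159   8.306
    5ICG     C1   13   0.459   9.578   1.111
    5ICG     C2   14   0.459   9.578   2.011
    5ICG     C3   15   0.459   9.578   2.911
    6ICG     C1   16   2.984   8.956   4.761
    6ICG     C2   17   2.984   8.956   5.661
    6ICG     C3   18   2.984   8.956   6.561
    7ICG     C1   19   4.555   3.995  -0.070
    7ICG     C2   20   4.555   3.995   0.830
    7ICG     C3   21   4.555   3.995   1.730
    8ICG     C1   22   6.304   4.651   4.824
    8ICG     C2   23   6.304   4.651   5.724
    8ICG     C3   24   6.304   4.651   6.624
    9ICG     C1   25   6.622   8.779   2.889
    9ICG     C2   26   6.622   8.779   3.789
    9ICG     C3   27   6.622   8.779   4.689
   10ICG     C1   28   7.236   8.579   0.963
   10ICG     C2   29   7.236   8.579   1.863
   10ICG     C3   30   7.236   8.579   2.763
   11ICG     C1   31   6.327   7.181   4.518
   11ICG     C2   32   6.327   7.181   5.418
   11ICG     C3   33   6.327   7.181   6.318
   12ICG     C1   34   2.047   9.000   0.336
   12ICG     C2   35   2.047   9.000   1.236
   12ICG     C3   36   2.047   9.000   2.136
   13ICG     C1   37   9.515   7.817   8.721
   13ICG     C2   38   9.515   7.817   9.621
   13ICG     C3   39   9.515   7.817  10.521
   14ICG     C1   40   1.143   9.776   5.305
   14ICG     C2   41   1.143   9.776   6.205
   14ICG     C3   42   1.143   9.776   7.105
   15ICG     C1   43   9.274   2.022   1.255
   15ICG     C2   44   9.274   2.022   2.155
   15ICG     C3   45   9.274   2.022   3.055
  10.00000  10.00000  10.00000
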