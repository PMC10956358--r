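30
frame 1
C 1.46935865 1.98393876 -1.06136281
N -1.19562415 2.57502622 0.52691193
O 1.53250897 3.75500543 -0.24107391
H -1.19643616 -3.64410894 -4.81365155
S 4.91605818 4.56945877 3.80928128
C 1.86382191 -3.70794859 -0.55063290
N 0.60811291 4.99755923 -1.74261814
O 3.32681336 -1.51075298 0.24171036
H -0.61867426 -1.73543614 -1.47675270
S -1.13689511 0.81530536 -0.49577949
C -0.91278498 -0.90384797 2.87825773
N 0.16248697 -1.24763794 -2.24967337
O -5.64279185 -2.19421337 -4.14098016
H -0.10126942 -2.50310725 1.42904314
S 6.93448429 1.88367077 -3.58580652
C 2.91702051 2.39274225 1.82570620
N 2.89382412 -2.18971294 -1.33783833
O -1.63239750 -2.50710319 0.45201998
H 2.01366975 -1.02935900 -2.91166245
S 1.50245601 4.45202107 1.45983149
C -6.09190769 4.59843272 2.48948445
N 0.68325556 -3.63031519 0.02285949
O -2.34907543 6.99062192 3.11753600
H 3.82077634 -0.20957070 -0.08075451
S 4.31313200 0.75385766 -0.41071717
C 1.28102594 1.02002071 0.17787663
N -5.23336959 -1.58366279 -2.60523621
O -0.07594818 0.99806549 -2.79357771
H -4.46496528 -7.30996787 2.57533882
S -1.62472847 2.41488501 -4.25643724
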