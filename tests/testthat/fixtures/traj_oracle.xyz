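12
frame 1
C -1.24611078 -1.09500234 0.54396751
C 0.42135901 -0.33778010 0.23008708
C -0.61986581 1.50946719 -0.10262953
N 0.70723324 2.93014157 -2.80731946
N 0.00244940 -3.07215224 -0.90582434
O -1.04413995 -2.06754809 2.67953343
O -4.40704515 0.42604613 1.36146641
H -2.58902449 -0.60943802 -3.51449380
H -1.24357242 1.13279495 -1.06731236
H -4.26635590 4.50223125 0.51249349
S 2.20416764 1.07260938 -0.12803744
C 0.29426492 -3.61138114 0.40358625
12
frame 2
C -0.07247737 -1.91998272 1.57974813
C 1.71747515 -1.58322104 0.46287939
C 0.54639857 0.99805292 1.36478848
N 1.44018164 2.86578946 -1.11559127
N 1.23499387 -3.65094050 -0.10443890
O 1.18387179 -3.06161501 2.73000894
O -1.66825689 -0.20129848 4.74512852
H -3.12885853 -0.39226663 -1.25417079
H 0.38327525 1.15097820 1.01733844
H -1.90147486 3.22283080 3.58494509
S 3.59378788 1.53382455 -0.15344994
C 0.43480704 -5.44003666 0.78122158
12
frame 3
C -1.33450786 -2.07612649 1.38837773
C -0.38551576 -1.77950505 1.85347345
C -1.19537590 0.73380357 1.35503981
N -0.10780135 1.77479714 -1.60358906
N -0.66248482 -4.10174494 -0.32070989
O -0.49718745 -3.70907942 3.85346958
O -4.26679404 -0.68528633 4.22149363
H -4.57138391 -0.87334322 -1.84990589
H -2.08604065 0.22112986 1.18950249
H -4.40033672 3.07973015 3.21079307
S 1.53153016 0.79819556 0.55903928
C -0.48517899 -5.01683568 0.32422659
12
frame 4
C -1.48225307 -1.61031490 1.41180616
C -0.32476624 -0.29516333 0.76938125
C -0.32349663 1.00680877 1.68886755
N 0.89464241 3.51271341 -0.66111507
N -0.95570336 -2.87841745 -0.13164713
O 0.01292417 -2.69867086 2.75214913
O -3.09476868 0.06314040 5.03413023
H -4.03838858 0.72469667 -1.00237884
H -1.16139143 1.24927323 1.20170705
H -3.53933724 4.44871166 4.18245078
S 2.53557577 1.15139795 0.19584930
C -0.41261943 -3.91525280 -0.27622021
12
frame 5
C -1.07103702 -2.70739212 0.83856015
C 0.16919808 -1.74825477 0.06084917
C -0.33197270 0.03337281 1.44728188
N 1.71878892 2.13072523 -0.25028747
N 0.49576586 -3.79232910 -1.28415421
O -1.40524403 -3.99361367 2.29027878
O -3.75430959 -1.53215299 3.44984191
H -3.10929659 0.29969526 -2.34263484
H -1.07294259 0.37423073 1.19682402
H -4.03821169 2.54224914 4.00140650
S 2.36584192 0.03964847 1.94247619
C -0.69717063 -5.10869063 -0.68815836
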