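##TITLE=synthetic SERS example (generated, not measured)
##JCAMP-DX=4.24
##DATA TYPE=RAMAN SPECTRUM
##XUNITS=1/CM
##YUNITS=ARBITRARY UNITS
##XFACTOR=1
##YFACTOR=0.001
##FIRSTX=600
##LASTX=1800
##NPOINTS=301
##XYDATA=(X++(Y..Y))
600 4408 4395 4360 4350 4332 4283 4291 4267
632 4264 4221 4217 4186 4151 4087 4105 4101
664 4081 4045 4054 4024 4003 3983 3932 3965
696 3906 3896 3898 3839 3856 3823 3821 3815
728 3752 3728 3732 3680 3702 3662 3651 3657
760 3601 3607 3604 3589 3571 3527 3504 3504
792 3451 3488 3439 3397 3411 3389 3390 3378
824 3363 3353 3320 3311 3314 3259 3275 3230
856 3264 3199 3217 3227 3189 3233 3257 3198
888 3223 3250 3333 3383 3552 3676 3853 3834
920 3723 3522 3333 3234 3192 3156 3143 3118
952 3200 3251 3381 3544 3619 3671 3774 3730
984 3782 3832 3859 3774 3730 3797 4114 4385
1016 4253 3830 3485 3156 2997 2875 2850 2720
1048 2692 2690 2604 2622 2585 2572 2554 2545
1080 2530 2515 2469 2486 2499 2491 2459 2439
1112 2503 2463 2620 2695 2687 2679 2580 2479
1144 2442 2376 2365 2344 2328 2350 2348 2382
1176 2467 2562 2715 2838 2873 2937 2954 2935
1208 2836 2859 3005 3117 3046 2821 2565 2387
1240 2265 2218 2163 2138 2088 2069 2077 2061
1272 2038 2041 2009 2075 2101 2177 2247 2350
1304 2424 2458 2429 2396 2510 2623 2606 2542
1336 2568 2651 2914 3209 3361 3267 2956 2772
1368 2684 2555 2329 2173 2013 1914 1903 1842
1400 1816 1831 1810 1783 1775 1793 1876 1880
1432 1979 2163 2380 2701 2979 2902 2673 2372
1464 2202 2166 2110 2046 1905 1836 1728 1640
1496 1611 1574 1579 1520 1552 1504 1522 1505
1528 1497 1505 1485 1545 1542 1591 1648 1761
1560 1912 2086 2207 2264 2457 2686 2849 2698
1592 2296 2011 1768 1660 1647 1501 1530 1545
1624 1595 1674 1754 1679 1542 1446 1364 1352
1656 1312 1262 1261 1210 1227 1199 1209 1214
1688 1189 1111 1162 1173 1106 1144 1132 1131
1720 1103 1094 1105 1101 1095 1089 1087 1079
1752 1075 1031 1061 1058 1059 1020 1018 1020
1784 1035 958 997 976 993
##END=
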