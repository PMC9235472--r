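carbohydrate 0.0847 -0.2516 0.1652 -0.7577 0.1003 0.4225 -0.0718 0.1055 0.2624 0.2334
energy 0.0813 -0.6068 -0.0154 -0.2924 -0.2824 -0.0501 -0.3517 -0.1049 -0.5551 0.1197
lipid -0.2341 -0.6536 -0.1899 -0.0222 -0.0278 -0.224 -0.416 -0.07 0.4941 -0.0918
nucleotide 0.1568 -0.1139 0.1621 -0.6342 0.1269 0.0384 0.1897 -0.4579 -0.2917 -0.431
amino -0.0073 0.3108 -0.2354 -0.2709 -0.3453 0.0142 0.1137 -0.395 -0.6231 0.3129
glycan -0.0685 -0.7163 0.0342 0.1253 0.1459 0.1717 0.2619 0.5058 -0.2584 0.1533
cofactors -0.3805 0.2313 -0.4367 -0.3277 -0.1471 -0.3234 -0.0715 0.092 -0.3545 -0.4881
vitamins 0.1708 -0.2228 0.0073 -0.1684 0.2983 0.0796 -0.0948 -0.1091 -0.5841 0.6598
terpenoids -0.1318 0.4934 -0.4178 -0.3539 0.3907 0.2363 0.2749 0.3596 0.042 -0.1556
polyketides 0.252 -0.577 0.1181 -0.1723 0.1862 -0.2484 -0.1958 0.6283 -0.0834 0.1532
secondary -0.1697 0.1987 0.1903 0.4118 -0.1063 -0.4826 0.4014 0.3654 0.0894 0.4232
xenobiotics 0.3518 -0.7302 -0.0692 0.0776 -0.1786 0.3205 0.3634 0.2317 -0.0667 0.0862
sulfur -0.5269 0.0514 -0.1745 -0.453 0.1832 0.1999 0.3716 0.3654 0.3499 0.1284
phosphate 0.0011 -0.2873 0.262 0.2352 0.0525 -0.2565 -0.3382 -0.2725 -0.1804 -0.7098
sugar -0.0247 0.1751 -0.1359 0.2521 -0.0788 0.4207 -0.3608 0.4112 0.6168 -0.1544
glucose 0.3389 -0.3409 0.1732 0.2132 -0.0103 0.1178 -0.439 -0.1643 -0.6325 -0.2444
fatty 0.0519 -0.6206 -0.3246 -0.2988 -0.0146 -0.2069 -0.4138 -0.2653 0.2829 -0.2299
sterol -0.2033 -0.0155 0.0775 0.1938 -0.5722 0.5302 0.3423 0.1372 0.0985 -0.4007
purine -0.269 0.0847 -0.035 0.3981 0.565 -0.5252 0.102 0.2327 0.0909 -0.3048
pyrimidine -0.0964 -0.2003 -0.2748 -0.2776 0.0951 0.2698 -0.4529 0.6806 -0.0296 -0.2167
protein -0.5167 0.1399 0.0128 -0.0361 0.3709 -0.164 0.3168 -0.2124 -0.3595 0.5224
enzyme 0.1349 0.5553 0.1898 0.0837 0.1025 0.1731 -0.4719 0.1409 -0.5809 0.0992
vitamin -0.2784 0.5615 0.3143 0.3817 -0.3855 -0.0771 -0.1889 -0.1489 0.3847 0.0482
terpene -0.2653 0.2997 0.1231 0.5891 -0.1017 -0.3842 0.1326 -0.3232 0.4431 -0.0352
antibiotic -0.0087 -0.292 0.4136 0.1749 -0.3207 0.069 -0.303 0.2542 -0.5323 -0.4071
drug 0.2958 -0.031 -0.683 0.044 -0.5236 -0.0274 -0.2531 0.0948 0.2765 0.1368
oxidative 0.435 0.3114 0.1477 -0.5336 -0.2414 -0.4366 0.3391 0.1871 -0.0828 -0.038
phosphorylation 0.016 -0.7211 -0.0585 0.1493 0.1958 0.2342 0.4537 0.0542 0.3896 0.0189
metabolism -0.1271 -0.0467 0.1436 -0.0286 -0.1691 -0.0594 -0.1242 -0.0404 0.0816 -0.1792
of -0.0454 0.012 0.2273 0.1749 0.1571 -0.0317 0.0548 -0.0791 0.0648 0.0369
and -0.025 -0.1098 -0.0451 -0.0661 -0.0089 -0.0385 -0.3257 0.0224 -0.0552 -0.0255
other 0.0013 -0.0665 0.1228 0.0578 0.0372 0.0744 0.114 0.0326 0.3104 0.0506
biosynthesis 0.0122 0.0684 -0.0303 -0.065 -0.1672 -0.0938 -0.2197 4e-04 0.1201 -0.1213
biodegradation -0.0476 0.0481 -0.2807 0.0647 0.0207 0.2959 -0.1313 -0.2383 0.1697 -0.0962
metabolites 0.0585 0.1888 -0.3542 0.0622 0.0711 0.06 0.2853 0.1774 0.0727 0.045
pathway 0.0695 0.0687 0.0995 0.097 -2e-04 -0.0277 -0.2114 -0.0318 0.1163 0.1352
pathways 0.1558 0.0433 -0.0358 -0.0699 -0.2087 -0.1079 -0.093 0.1664 -0.0031 0.0113
compound 0.0355 -0.0173 -0.076 -0.0761 -0.1196 0.0553 0.0868 -0.0427 -0.0205 0.001
acid 0.3137 0.2035 0.1938 -0.1164 -0.3232 -0.2556 -0.5338 -0.1522 -0.0554 -0.5729
acids 0.3063 0.1741 0.2031 -0.15 -0.3397 -0.1768 -0.5987 -0.182 -0.0637 -0.6035
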