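quinine
     RDKit          2D

 24 27  0  0  0  0  0  0  0  0999 V2000
   -6.5426   -2.3561    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.0447   -2.2754    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3657   -0.9379    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1846    0.3189    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.5056    1.6564    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0077    1.7372    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3287    3.0747    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8309    3.1554    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0121    1.8986    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6911    0.5611    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1277   -0.6957    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5513   -2.0332    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.6256   -0.6149    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3046    0.7226    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.8024    0.8033    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.6212   -0.4535    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9422   -1.7910    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4444   -1.8717    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.8614   -1.1618    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4754    0.0476    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.1190   -0.3728    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.7980    0.9648    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1889    0.4804    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8679   -0.8571    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  4  0
  4  5  4  0
  5  6  4  0
  6  7  4  0
  7  8  4  0
  8  9  4  0
  9 10  4  0
 10 11  1  0
 11 12  1  0
 11 13  1  0
 13 14  1  0
 14 15  1  0
 15 16  1  0
 16 17  1  0
 17 18  1  0
 18 19  1  0
 19 20  1  0
 20 21  1  0
 21 22  2  0
 10 23  4  0
 23 24  4  0
 24  3  4  0
 23  6  4  0
 18 13  1  0
 20 15  1  0
M  END
$$$$
dopamine
     RDKit          2D

 11 11  0  0  0  0  0  0  0  0999 V2000
   -4.7486   -0.0835    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3132    0.3521    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2183   -0.6732    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7829   -0.2376    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4425    1.2233    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9929    1.6589    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0878    0.6336    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5232    1.0692    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.7474   -0.8273    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8423   -1.8525    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.3120   -1.2629    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  4  0
  5  6  4  0
  6  7  4  0
  7  8  1  0
  7  9  4  0
  9 10  1  0
  9 11  4  0
 11  4  4  0
M  END
$$$$
strychnine
     RDKit          2D

 25 31  0  0  0  0  0  0  0  0999 V2000
    3.1453   -3.2884    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.8621   -2.5116    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5478   -3.2345    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7354   -2.4577    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9273   -3.3684    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3825   -3.0044    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.0051   -1.6398    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3264   -0.3021    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3237    0.8184    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8519    2.2423    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1030    3.5420    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6355    3.2313    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9522    1.2253    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3829    2.5457    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3857    1.4252    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8574    0.0013    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7043   -0.9580    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6100   -0.2351    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8932   -1.0119    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.0285   -0.0316    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.5167   -0.2192    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.4233    0.9757    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.8418    2.3584    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3536    2.5461    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4469    1.3511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  1  0
 10 11  1  0
 11 12  1  0
 12 13  1  0
 13 14  1  0
 14 15  1  0
 15 16  1  0
 16 17  1  0
 17 18  1  0
 18 19  1  0
 19 20  1  0
 20 21  4  0
 21 22  4  0
 22 23  4  0
 23 24  4  0
 24 25  4  0
 19  2  1  0
 25 20  4  0
 17  4  1  0
 16  8  1  0
 14 10  1  0
 18 13  1  0
 25 13  1  0
M  END
$$$$
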