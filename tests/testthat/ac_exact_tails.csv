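x,y,N1,N2,p_down,p_up
0,0,2,1,6.66666666666666630e-01,1.00000000000000000e+00
0,2,2,1,9.62962962962962910e-01,1.11111111111111105e-01
0,5,2,1,9.98628257887517190e-01,4.11522633744856002e-03
0,12,2,1,9.99999372774525663e-01,1.88167642315892079e-06
0,30,2,1,9.99999999999998335e-01,4.85693574961886143e-15
1,0,2,1,4.44444444444444420e-01,1.00000000000000000e+00
1,2,2,1,8.88888888888888840e-01,2.59259259259259245e-01
1,5,2,1,9.93141289437585728e-01,1.78326474622770917e-02
1,12,2,1,9.99993936820414264e-01,1.69350878084302856e-05
1,30,2,1,9.99999999999964917e-01,1.01995650741996088e-13
3,0,2,1,1.97530864197530853e-01,1.00000000000000000e+00
3,2,2,1,6.80384087791495173e-01,5.39094650205761305e-01
3,5,2,1,9.57577605039882096e-01,8.79439109891784754e-02
3,12,2,1,9.99884009748384761e-01,2.85108823968264612e-04
3,30,2,1,9.99999999996990852e-01,8.24365905917716772e-12
7,0,2,1,3.90184423106233816e-02,1.00000000000000000e+00
7,2,2,1,2.99141391048112604e-01,8.56932378194380950e-01
7,5,2,1,7.58691933817676856e-01,3.68479285565095682e-01
7,12,2,1,9.96275431025710811e-01,7.42406011469362408e-03
7,30,2,1,9.99999998660556222e-01,3.29053935886990681e-09
15,0,2,1,1.52243884034744472e-03,1.00000000000000000e+00
15,2,2,1,3.26478551318952065e-02,9.90357887344466170e-01
15,5,2,1,2.48646215048843794e-01,8.48489142073570957e-01
15,12,2,1,8.96076466010800599e-01,1.53723725655183635e-01
15,30,2,1,9.99997548895137589e-01,5.00118828827561896e-06
30,0,2,1,3.47673003389770891e-06,1.00000000000000000e+00
30,2,2,1,2.31009395585647772e-04,9.99960597059615819e-01
30,5,2,1,7.56882697626430883e-03,9.97075855428526947e-01
30,12,2,1,2.80832064590640140e-01,7.91511031073527827e-01
30,30,2,1,9.96444022512874117e-01,5.55302329716047399e-03
0,0,1,1,5.00000000000000000e-01,1.00000000000000000e+00
0,2,1,1,8.75000000000000000e-01,2.50000000000000000e-01
0,5,1,1,9.84375000000000000e-01,3.12500000000000000e-02
0,12,1,1,9.99877929687500000e-01,2.44140625000000000e-04
0,30,1,1,9.99999999534338713e-01,9.31322574615478516e-10
1,0,1,1,2.50000000000000000e-01,1.00000000000000000e+00
1,2,1,1,6.87500000000000000e-01,5.00000000000000000e-01
1,5,1,1,9.37500000000000000e-01,1.09375000000000000e-01
1,12,1,1,9.99084472656250000e-01,1.70898437500000000e-03
1,30,1,1,9.99999992316588759e-01,1.49011611938476562e-08
3,0,1,1,6.25000000000000000e-02,1.00000000000000000e+00
3,2,1,1,3.43750000000000000e-01,8.12500000000000000e-01
3,5,1,1,7.46093750000000000e-01,3.63281250000000000e-01
3,12,1,1,9.89364624023437500e-01,1.75781250000000000e-02
3,30,1,1,9.99999616993591189e-01,7.00587406754493713e-07
7,0,1,1,3.90625000000000000e-03,1.00000000000000000e+00
7,2,1,1,5.46875000000000000e-02,9.80468750000000000e-01
7,5,1,1,2.90527343750000000e-01,8.06152343750000000e-01
7,12,1,1,8.68412017822265625e-01,1.79641723632812500e-01
7,30,1,1,9.99941916496027261e-01,9.55382129177451134e-05
15,0,1,1,1.52587890625000000e-05,1.00000000000000000e+00
15,2,1,1,6.56127929687500000e-04,9.99862670898437500e-01
15,5,1,1,1.33018493652343750e-02,9.94091033935546875e-01
15,12,1,1,2.85794094204902649e-01,7.78965830802917480e-01
15,30,1,1,9.87051959103382615e-01,1.78489017775973480e-02
30,0,1,1,4.65661287307739258e-10,1.00000000000000000e+00
30,2,1,1,6.54254108667373657e-08,9.99999992316588759e-01
30,5,1,1,6.45674299448728561e-06,9.99998267274349928e-01
30,12,1,1,2.70078632729564561e-03,9.98556376012857072e-01
30,30,1,1,5.00000000000000000e-01,5.51289086504284764e-01
0,0,1,2,3.33333333333333315e-01,1.00000000000000000e+00
0,2,1,2,7.03703703703703720e-01,4.44444444444444420e-01
0,5,1,2,9.12208504801097386e-01,1.31687242798353921e-01
0,12,1,2,9.94861768913827382e-01,7.70734662925893956e-03
0,30,1,2,9.99996523269966131e-01,5.21509505084656357e-06
1,0,1,2,1.11111111111111105e-01,1.00000000000000000e+00
1,2,1,2,4.07407407407407385e-01,7.40740740740740700e-01
1,5,1,2,7.36625514403292159e-01,3.51165980795610400e-01
1,12,1,2,9.72596100873746039e-01,3.85367331462946952e-02
1,30,1,2,9.99960597059615819e-01,5.73660455593121951e-05
3,0,1,2,1.23456790123456783e-02,1.00000000000000000e+00
3,2,1,2,1.00137174211248292e-01,9.54732510288065828e-01
3,5,1,2,3.49692628156276997e-01,7.41350403901844257e-01
3,12,1,2,8.34054166402128483e-01,2.09240188120251941e-01
3,30,1,2,9.99066433602008974e-01,1.28484489919375336e-03
7,0,1,2,1.52415790275872584e-04,1.00000000000000000e+00
7,2,1,2,3.40395264949448773e-03,9.99034699994919451e-01
7,5,1,2,3.46548346853178466e-02,9.81241567737528686e-01
7,12,1,2,3.38528517180893496e-01,7.20663341065577945e-01
7,30,1,2,9.66774832121079064e-01,4.14086559254579212e-02
15,0,1,2,2.32305731254187731e-08,1.00000000000000000e+00
15,2,1,2,1.67518243982186506e-06,9.99999728976646907e-01
15,5,1,2,7.25072074796172700e-05,9.99974922166115276e-01
15,12,1,2,8.15393463153740033e-03,9.94958577347586637e-01
15,30,1,2,4.72282767666564574e-01,5.69497799182216213e-01
30,0,1,2,1.61897858320628708e-15,1.00000000000000000e+00
30,2,1,2,3.91972703645166591e-13,9.99999999999964917e-01
30,5,1,2,8.70513258128502205e-11,9.99999999982159826e-01
30,12,1,2,2.34270975220454071e-07,9.99999903712529337e-01
30,30,1,2,3.55597748712587446e-03,9.97442545417891457e-01
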