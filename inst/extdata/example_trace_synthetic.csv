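time_s,current_A
0.00e+00,-4.83261487001721e-08
1.00e-04,-5.49766113419307e-08
2.00e-04,-3.93263606847755e-08
3.00e-04,-5.21654522665303e-08
4.00e-04,-3.54779709167250e-08
5.00e-04,-4.34443388832465e-08
6.00e-04,-3.18575838207145e-08
7.00e-04,-4.59730949687876e-08
8.00e-04,-6.03199962901902e-08
9.00e-04,-3.91490436771545e-08
1.00e-03,-3.62966753330380e-08
1.10e-03,-2.42991060413116e-08
1.20e-03,-2.96379591974160e-08
1.30e-03,-4.47336542849359e-08
1.40e-03,-4.40423192063046e-08
1.50e-03,-4.54828215890608e-08
1.60e-03,-3.94234314072464e-08
1.70e-03,-4.02351762716559e-08
1.80e-03,-3.68554451927927e-08
1.90e-03,-4.33160803526478e-08
2.00e-03,-2.25980453177781e-08
2.10e-03,-4.13566613615627e-08
2.20e-03,-4.78478783165466e-08
2.30e-03,-3.56344539925102e-08
2.40e-03,-4.31528151958659e-08
2.50e-03,-5.21621813653631e-08
2.60e-03,-4.74683561111909e-08
2.70e-03,-1.95799450556155e-09
2.80e-03,-5.65242450011424e-10
2.90e-03,-5.79055245391482e-09
3.00e-03,2.76253664565461e-09
3.10e-03,-1.68976388983169e-08
3.20e-03,-7.69662395471532e-09
3.30e-03,2.73973910197814e-09
3.40e-03,-4.71965681593466e-09
3.50e-03,-1.37159107814385e-08
3.60e-03,-6.59488421081942e-09
3.70e-03,-1.73181788379874e-09
3.80e-03,5.53516239740714e-09
3.90e-03,1.75887225884889e-09
4.00e-03,1.58042335289919e-09
4.10e-03,-1.16109940919976e-08
4.20e-03,-7.79549334149627e-10
4.30e-03,1.07846944291390e-08
4.40e-03,-9.93308427033104e-09
4.50e-03,1.19566627288534e-08
4.60e-03,2.01114918599183e-09
4.70e-03,-4.32025991719964e-09
4.80e-03,1.35553031035283e-08
4.90e-03,8.01402106594528e-09
5.00e-03,-9.00268205442788e-10
5.10e-03,-1.74123483091729e-10
5.20e-03,1.89089630032489e-09
5.30e-03,-2.56544516840774e-09
5.40e-03,-1.26981940015504e-09
5.50e-03,1.01980947298169e-09
5.60e-03,3.48151459798642e-09
5.70e-03,1.24076891425673e-08
5.80e-03,1.83642386221254e-09
5.90e-03,-1.33726569054591e-08
6.00e-03,5.54741972763368e-09
6.10e-03,8.75160839807929e-09
6.20e-03,-1.11430246681519e-08
6.30e-03,1.48812247426163e-08
6.40e-03,3.12376203902771e-09
6.50e-03,1.02581998517669e-08
6.60e-03,2.23170170119523e-09
6.70e-03,-4.51847396468845e-09
6.80e-03,-5.53093406854475e-10
6.90e-03,-1.06590049486190e-08
7.00e-03,-3.37932465082641e-08
7.10e-03,-3.64102068067471e-08
7.20e-03,-3.17987656383482e-08
7.30e-03,-2.49118479654113e-08
7.40e-03,-1.66651996785710e-08
7.50e-03,-3.68038402755638e-08
7.60e-03,-3.65562435240761e-08
7.70e-03,-1.74008795267675e-08
7.80e-03,-3.39384489137087e-08
7.90e-03,-3.09092767192270e-08
8.00e-03,-4.31385532054140e-08
8.10e-03,-4.46861223072619e-08
8.20e-03,1.25301087384223e-08
8.30e-03,1.36764335254248e-08
8.40e-03,2.24608191171072e-08
8.50e-03,-1.08803387107179e-08
8.60e-03,-3.44312666943449e-09
8.70e-03,-1.98750738535105e-11
8.80e-03,1.39364317741756e-08
8.90e-03,2.20225211817422e-08
9.00e-03,-5.15545217188242e-09
9.10e-03,3.98994010423767e-09
9.20e-03,1.60133107266010e-08
9.30e-03,8.37503490997840e-09
9.40e-03,8.78307566982428e-09
9.50e-03,1.24403515803541e-08
9.60e-03,8.59632038416805e-09
9.70e-03,1.82201673044216e-08
9.80e-03,-4.87744653014482e-09
9.90e-03,5.13659084841607e-09
1.00e-02,-1.49025061138729e-08
1.01e-02,-8.96938497450013e-10
1.02e-02,-5.35432094485914e-09
1.03e-02,-1.79223369543326e-08
1.04e-02,-4.30622083031597e-08
1.05e-02,-4.01455093067550e-08
1.06e-02,6.58880291389261e-09
1.07e-02,-9.56919986545036e-09
1.08e-02,-8.07917460466420e-09
1.09e-02,-6.14115991638578e-09
1.10e-02,-3.28577754538200e-09
1.11e-02,-1.80001609897810e-08
1.12e-02,2.34994847455342e-09
1.13e-02,4.49261617026680e-09
1.14e-02,-5.70255200781629e-09
1.15e-02,-2.65251856394149e-08
1.16e-02,-1.39327939854796e-08
1.17e-02,-7.93407909252748e-10
1.18e-02,-1.37025119392419e-08
1.19e-02,2.71654080323216e-10
1.20e-02,-5.75596182337562e-09
1.21e-02,5.12102048123286e-09
1.22e-02,-6.89710230888549e-09
1.23e-02,-5.83039501156858e-09
1.24e-02,-1.45187768403486e-08
1.25e-02,-6.58550226375491e-09
1.26e-02,1.64246544452565e-08
1.27e-02,1.93074732364571e-08
1.28e-02,-1.34111324690852e-08
1.29e-02,-2.40270157641452e-08
1.30e-02,-8.45402078797244e-09
1.31e-02,-7.65978193015772e-09
1.32e-02,-1.00023796053085e-08
1.33e-02,-1.86354393283705e-09
1.34e-02,-2.95998557448819e-09
1.35e-02,7.80855259318265e-09
1.36e-02,-3.91433341252946e-08
1.37e-02,-5.10360308328088e-08
1.38e-02,-1.64319646660411e-08
1.39e-02,-9.53959253780122e-09
1.40e-02,-5.49790480949412e-08
1.41e-02,-4.40044873125858e-08
1.42e-02,-3.66386899655709e-08
1.43e-02,-3.28978599392102e-08
1.44e-02,-5.39415965014245e-08
1.45e-02,-5.57495564787995e-08
1.46e-02,-3.67808382227929e-08
1.47e-02,-3.74792759094647e-08
1.48e-02,-4.58084305574822e-08
1.49e-02,-3.21307107521302e-08
1.50e-02,-3.36526251874727e-08
1.51e-02,-3.86369864281856e-08
1.52e-02,6.06595751275553e-09
1.53e-02,1.81679733749667e-09
1.54e-02,-2.21593836117626e-09
1.55e-02,3.32364833285133e-09
1.56e-02,-1.03984008775012e-08
1.57e-02,3.15983998041452e-09
1.58e-02,-4.13304116002623e-09
1.59e-02,1.15216949374790e-08
1.60e-02,-6.81700192701224e-09
1.61e-02,-9.29417163799407e-09
1.62e-02,-9.56277368528740e-09
1.63e-02,1.42334773165604e-09
1.64e-02,1.03549348534726e-08
1.65e-02,-1.01007773558319e-08
1.66e-02,1.92115257488145e-09
1.67e-02,-3.29998188542788e-09
1.68e-02,9.27516488408266e-09
1.69e-02,7.92717221604341e-09
1.70e-02,-4.63554396440507e-09
1.71e-02,-1.27286834710234e-08
1.72e-02,8.58642904210443e-09
1.73e-02,-2.38059219217991e-09
1.74e-02,2.88917163988604e-10
1.75e-02,9.40338103214107e-09
1.76e-02,-1.44682069904404e-10
1.77e-02,1.21609692049177e-10
1.78e-02,8.74907743994290e-10
1.79e-02,-2.12803848562122e-09
1.80e-02,9.50141038104453e-09
1.81e-02,7.57957958163738e-09
1.82e-02,-8.07468925442051e-10
1.83e-02,-1.22105393658824e-08
1.84e-02,2.04845777157765e-09
1.85e-02,-9.60520439886993e-10
1.86e-02,2.07804876778742e-09
1.87e-02,2.40434068690236e-08
1.88e-02,-3.37869307802125e-09
1.89e-02,7.87644790548035e-09
1.90e-02,1.27183252588012e-09
1.91e-02,-1.61657305821323e-10
1.92e-02,-2.11279256110154e-08
1.93e-02,8.06803595170527e-09
1.94e-02,-4.00634994044377e-09
1.95e-02,-1.23147501314638e-08
1.96e-02,-1.44450568641854e-08
1.97e-02,-2.45550493697184e-08
1.98e-02,-7.56996407563163e-09
1.99e-02,-1.49631020243799e-09
2.00e-02,-1.77427653550452e-10
2.01e-02,3.94564355820138e-09
2.02e-02,1.18220937575640e-08
2.03e-02,-1.92457678628413e-08
2.04e-02,1.20334997895554e-08
2.05e-02,-1.01766201916392e-10
2.06e-02,-1.94740733373819e-08
2.07e-02,-5.24116230937134e-09
2.08e-02,1.62260127316991e-08
2.09e-02,4.57638080097446e-09
2.10e-02,9.78062637166847e-10
2.11e-02,-5.83279237832984e-09
2.12e-02,-1.18015005979466e-08
2.13e-02,2.91498794926586e-09
2.14e-02,-3.48339395446430e-09
2.15e-02,1.70724375231119e-08
2.16e-02,1.44989063518599e-09
2.17e-02,-7.93707470503142e-09
2.18e-02,1.66341327659381e-08
2.19e-02,8.77466734590173e-09
2.20e-02,3.91743732417159e-09
2.21e-02,1.37445208959081e-08
2.22e-02,-1.01761042398825e-08
2.23e-02,-1.50949091851685e-08
2.24e-02,2.47666048569586e-08
2.25e-02,8.62307297036272e-09
2.26e-02,1.05917885093549e-08
2.27e-02,9.75187049826879e-10
2.28e-02,7.61681629219004e-10
2.29e-02,-1.11432690068008e-08
2.30e-02,-1.76957087385053e-08
2.31e-02,-1.41734825390815e-08
2.32e-02,-5.69020659645989e-09
2.33e-02,-1.02858132498265e-08
2.34e-02,-8.02717298238222e-09
2.35e-02,-2.26398060810926e-08
2.36e-02,-2.45291400735172e-09
2.37e-02,1.62033111385599e-08
2.38e-02,-1.46165574766713e-08
2.39e-02,-4.28385323104290e-08
2.40e-02,-4.45579445858393e-08
2.41e-02,-4.26341079008392e-08
2.42e-02,-4.20167362428734e-08
2.43e-02,1.49443801656959e-08
2.44e-02,-5.35282904793666e-08
2.45e-02,-4.57410128188668e-08
2.46e-02,-3.89727495285300e-08
2.47e-02,-5.54385474132399e-08
2.48e-02,-6.01025351391649e-08
2.49e-02,-4.18985012467770e-08
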