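# STO-nG expansion tables (zeta = 1), generated by data-raw/fit_sto_ng.R via
# deterministic maximum-overlap fits.  Do not edit by hand.
.sto_ng_table <- list(
  n1l0g3 = list(alpha = c(2.227660348416e+00, 4.057711181865e-01, 1.098174899463e-01),
    coef = c(1.543289756649e-01, 5.353282130182e-01, 4.446344684225e-01)),
  n1l0g4 = list(alpha = c(5.216848241366e+00, 9.546183286710e-01, 2.652034107283e-01, 8.801862355562e-02),
    coef = c(5.675240083023e-02, 2.601413784996e-01, 5.328461255130e-01, 2.916254321800e-01)),
  n1l0g6 = list(alpha = c(2.310331123127e+01, 4.235950741592e+00, 1.185062353296e+00, 4.071003309315e-01, 1.580890296954e-01, 6.510981579106e-02),
    coef = c(9.163473261033e-03, 4.936114004124e-02, 1.685378167578e-01, 3.705620775567e-01, 4.164917539385e-01, 1.303355429035e-01)),
  n2l0g3 = list(alpha = c(2.581577490951e+00, 1.567622510753e-01, 6.018333978615e-02),
    coef = c(-5.994476089483e-02, 5.960382936596e-01, 4.581788857092e-01)),
  n2l0g4 = list(alpha = c(1.161526087558e+01, 2.000244332932e+00, 1.607280417099e-01, 6.125744355945e-02),
    coef = c(-1.198410661864e-02, -5.472051614105e-02, 5.805587885351e-01, 4.770079026203e-01)),
  n2l0g6 = list(alpha = c(2.768488910916e+01, 5.077130362659e+00, 1.426794795857e+00, 2.040320111557e-01, 9.260209961379e-02, 4.416141927010e-02),
    coef = c(-4.151311741892e-03, -2.067013655987e-02, -5.150281447550e-02, 3.346332214484e-01, 5.621052748982e-01, 1.712939491643e-01)),
  n2l1g3 = list(alpha = c(9.192379440800e-01, 2.359194033468e-01, 8.009804461440e-02),
    coef = c(1.623948854730e-01, 5.661709922712e-01, 4.223070465448e-01)),
  n2l1g4 = list(alpha = c(1.798259611676e+00, 4.662619708295e-01, 1.643717789226e-01, 6.543923635543e-02),
    coef = c(5.713176291755e-02, 2.857457068915e-01, 5.517873922601e-01, 2.632311985329e-01)),
  n2l1g6 = list(alpha = c(5.868187449400e+00, 1.530325243059e+00, 5.475692643528e-01, 2.288951550650e-01, 1.046665504181e-01, 4.948268122495e-02),
    coef = c(7.924380111079e-03, 5.144080524262e-02, 1.898376876129e-01, 4.049833950967e-01, 4.012382433558e-01, 1.051888617656e-01)),
  n3l0g3 = list(alpha = c(5.641490110740e-01, 6.924419594950e-02, 3.269527776913e-02),
    coef = c(-1.782577490821e-01, 8.612764490926e-01, 2.261838573271e-01)),
  n3l0g4 = list(alpha = c(1.513258264074e+00, 4.262493336820e-01, 7.643318572905e-02, 3.760542280322e-02),
    coef = c(-3.295516139723e-02, -1.724515122895e-01, 7.518518140190e-01, 3.589620678443e-01)),
  n3l0g6 = list(alpha = c(3.273057919862e+00, 9.200344740246e-01, 3.593290447885e-01, 8.636464522585e-02, 4.797043414916e-02, 2.724482483782e-02),
    coef = c(-6.775680566418e-03, -5.639689152460e-02, -1.587820672777e-01, 5.535104932794e-01, 5.015153833569e-01, 7.219849874683e-02)),
  n3l1g3 = list(alpha = c(2.692883690511e+00, 1.489359278550e-01, 5.739584100528e-02),
    coef = c(-1.061945151001e-02, 5.218565942411e-01, 5.450013393859e-01)),
  n3l1g4 = list(alpha = c(1.853179261407e+00, 1.915076416771e-01, 8.655492684895e-02, 4.184257213652e-02),
    coef = c(-1.434250052332e-02, 2.755174926232e-01, 5.846748819549e-01, 2.144991249316e-01)),
  n3l1g6 = list(alpha = c(5.078182957436e+00, 1.340818826760e+00, 2.248400807135e-01, 1.131723250053e-01, 6.076326392425e-02, 3.315388265254e-02),
    coef = c(-3.329739190179e-03, -1.419483226554e-02, 1.639472194975e-01, 4.485404166579e-01, 3.908729458821e-01, 7.411043726100e-02)),
  n3l2g3 = list(alpha = c(5.229109510848e-01, 1.639595304800e-01, 6.386628674574e-02),
    coef = c(1.686597394925e-01, 5.847985388060e-01, 4.056777571947e-01)),
  n3l2g4 = list(alpha = c(9.185851136857e-01, 2.920461954080e-01, 1.187568882348e-01, 5.286755291866e-02),
    coef = c(5.799052166687e-02, 3.045581135227e-01, 5.601359453984e-01, 2.432422692976e-01)),
  n3l2g6 = list(alpha = c(2.452330383700e+00, 7.856110505462e-01, 3.260958638656e-01, 1.538090641643e-01, 7.790546888368e-02, 4.024606050168e-02),
    coef = c(7.527085626722e-03, 5.556149728161e-02, 2.116747173283e-01, 4.290022580000e-01, 3.787884704384e-01, 8.577975303791e-02)),
  n4l0g3 = list(alpha = c(6.470040296911e+00, 2.445315861221e-01, 4.050500299563e-02),
    coef = c(6.096361679404e-04, -3.046414246863e-01, 1.146687040315e+00)),
  n4l0g4 = list(alpha = c(3.242203732423e-01, 1.663208746431e-01, 5.081109238965e-02, 2.829071250561e-02),
    coef = c(-1.120698106001e-01, -2.845424826769e-01, 8.909855800716e-01, 3.517842480432e-01)),
  n4l0g6 = list(alpha = c(8.415252132434e+00, 2.408959070248e+00, 3.840818147525e-01, 1.796226454593e-01, 4.998038070559e-02, 2.787131041927e-02),
    coef = c(2.077232356938e-04, 1.494702287232e-03, -7.127297872540e-02, -3.159414657634e-01, 9.039831461657e-01, 3.282103781336e-01)),
  n4l1g3 = list(alpha = c(4.859690241002e-01, 7.430218602576e-02, 3.653342115399e-02),
    coef = c(-6.147825317285e-02, 6.604169029269e-01, 3.932642873550e-01)),
  n4l1g4 = list(alpha = c(1.492601850937e+00, 4.327621016330e-01, 7.553153724175e-02, 3.706271003414e-02),
    coef = c(-6.035226451419e-03, -6.013305676550e-02, 6.451521802033e-01, 4.117919859651e-01)),
  n4l1g6 = list(alpha = c(2.390057566501e+00, 7.961244496889e-01, 3.415596033268e-01, 8.847395600415e-02, 4.958239246601e-02, 2.816932630832e-02),
    coef = c(-1.665573737492e-03, -1.657390147222e-02, -5.958557680422e-02, 4.053148392479e-01, 5.433916852950e-01, 1.204972302881e-01))
)
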