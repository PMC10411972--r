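# SWC morphology (id type x y z radius parent)
1 1 0 0 0 7 -1
2 3 9.3862815129857093 -2.1898150945494854 -2.0645703318489779 0.55200000000000005 1
3 3 18.8141278155558 -4.5862734164416494 -3.6560234574654222 0.55200000000000005 2
4 3 28.032237008268318 -7.2504127790000865 -5.9118704852092705 0.55200000000000005 3
5 3 37.219593682184822 -10.056810390283118 -8.1201800735849279 0.55200000000000005 4
6 3 46.241305104753337 -13.316713438113487 -10.387728655452166 0.55200000000000005 5
7 3 55.111354729435632 -17.255506674265796 -12.110560319602612 0.55200000000000005 6
8 3 3.5569124506405161 10.637418312895825 -0.70742861602758256 0.55200000000000005 1
9 3 6.8669200794658494 21.268389172035068 -2.2348636821034042 0.55200000000000005 8
10 3 9.8596061917308813 32.016303512574737 -3.5887163157771682 0.55200000000000005 9
11 3 13.350656162812912 42.697674049261245 -3.7549792077321569 0.55200000000000005 10
12 3 -9.3698968545922643 -2.2990436598913835 -4.809285714519465 0.55200000000000005 1
13 3 -17.991237427919941 -5.316259327311279 -10.534553763671024 0.55200000000000005 12
14 3 -26.592351328588506 -8.1440974712703529 -16.385533937877895 0.55200000000000005 13
15 3 -35.685429587332877 -10.888325102394287 -21.484057291613972 0.55200000000000005 14
16 3 -0.51126992710423824 -9.7990063684948794 -5.8184019523870543 0.55200000000000005 1
17 3 -1.1064253639657795 -19.520485510202445 -11.757623898991238 0.55200000000000005 16
18 3 -1.2136627985482598 -29.443666603208122 -17.383874973707396 0.55200000000000005 17
19 3 60.486564683777523 -22.891996166936373 -18.370233024289245 0.504 7
20 3 65.629970967163473 -27.541535794748249 -25.565617050001403 0.504 19
21 3 70.810423144128691 -31.925049323633516 -32.900064718933059 0.504 20
22 3 64.251248851488356 -18.619984892109606 -16.480663052602988 0.504 7
23 3 73.706174304864149 -18.907466547571737 -20.356098800381673 0.504 22
24 3 83.377602003098318 -18.881126573253219 -23.666696291751389 0.504 23
25 3 92.816486261357994 -19.594436393560397 -27.52621910237351 0.504 24
26 3 102.05081128195127 -19.743870934399649 -31.908247627877493 0.504 25
27 3 111.35592778475264 -19.278277562623476 -36.114824971482776 0.504 26
28 3 10.138512486136712 51.807642294996413 -5.3506452297260605 0.504 11
29 3 7.6595037971525031 61.165536512048938 -6.813474759799691 0.504 28
30 3 4.816359192100327 70.348110755237443 -8.6715375990905414 0.504 29
31 3 2.1037056299423922 79.551189855691618 -10.620995014412896 0.504 30
32 3 -0.53194028041527197 88.778404426827763 -12.561979399998629 0.504 31
33 3 18.002873759702936 50.00879966041596 -1.5141182858450257 0.504 11
34 3 22.538463788002655 57.43405469947983 0.58615661096758753 0.504 33
35 3 26.502169767655907 65.1404007962946 2.8263371137631568 0.504 34
36 3 31.24279563117987 72.330840985617087 5.2637907539377204 0.504 35
37 3 -44.618370642064761 -11.591759610820164 -20.148739946272087 0.504 15
38 3 -53.57513769670912 -11.667211145881986 -18.790079060537927 0.504 37
39 3 -62.483268036643111 -12.331038541901608 -17.280153419067112 0.504 38
40 3 -71.387814483876724 -13.358309656003319 -15.965202836375509 0.504 39
41 3 -80.396672175081477 -14.251569041250004 -15.621838339056419 0.504 40
42 3 -43.930656535955706 -8.2525319919505566 -25.594700063633439 0.504 15
43 3 -52.603999215937428 -5.6443546365781634 -28.725050586026217 0.504 42
44 3 -61.179637512368835 -3.0882421099444661 -32.153355314967321 0.504 43
45 3 -69.566284403714093 -0.43223296186933569 -35.953135055918715 0.504 44
46 3 -77.387046348719551 3.0598544131652829 -40.250758250103253 0.504 45
47 3 -84.92673286055215 5.7144366926081336 -45.536103743017797 0.504 46
48 3 117.25474245268191 -25.306750425114888 -41.121596731757649 0.45599999999999996 27
49 3 122.53966452197625 -31.785999083754326 -46.24948114356566 0.45599999999999996 48
50 3 127.2978802721295 -38.775628456351065 -51.220469687968603 0.45599999999999996 49
51 3 131.29875635770179 -45.386388624321924 -57.261752958046628 0.45599999999999996 50
52 3 117.40482143987731 -19.543155507627151 -43.069765281871064 0.45599999999999996 27
53 3 123.60896291611908 -19.851880291690133 -49.884733150342825 0.45599999999999996 52
54 3 129.06651461434592 -20.507207530440191 -57.288525770963325 0.45599999999999996 53
55 3 134.62112595578063 -21.102848154322409 -64.624871904469231 0.45599999999999996 54
56 3 140.04802824823051 -20.672293818105857 -72.067574637320263 0.45599999999999996 55
57 3 -2.2788741717762413 94.856033030063728 -20.7855208164179 0.45599999999999996 32
58 3 -4.190609919143613 100.86177053436819 -29.025203113014602 0.45599999999999996 57
59 3 -6.1075469144601904 107.14707470299895 -37.052424609335738 0.45599999999999996 58
60 3 -8.0918663722687381 113.86668236954414 -44.702609573393147 0.45599999999999996 59
61 3 -9.3125887378218302 120.45475399967928 -52.622403130656338 0.45599999999999996 60
62 3 -1.5510732358150794 98.531450825706429 -9.6157929288196637 0.45599999999999996 32
63 3 -2.4133034642644104 108.34501286105667 -6.8245351524936586 0.45599999999999996 62
64 3 -2.963043702002877 117.98084396186623 -3.4056017764094575 0.45599999999999996 63
65 3 -3.2526613800740112 127.76071402607816 -0.38718764145382956 0.45599999999999996 64
66 3 -2.6210221289048943 137.64675399772702 2.2027556586521229 0.45599999999999996 65
67 3 -2.4549032572541254 147.0919439494717 6.1526103469112918 0.45599999999999996 66
68 3 150.90425248693228 -20.434896595077269 -72.84903993434807 0.40799999999999997 56
69 3 161.76866407786642 -19.806537479138598 -73.156246342368718 0.40799999999999997 68
70 3 172.54245370548119 -18.339587649927719 -73.702291607355932 0.40799999999999997 69
71 3 182.97985468931259 -15.591111626533998 -75.127489988102155 0.40799999999999997 70
72 3 193.45771725771493 -13.299999816592154 -76.995604771768967 0.40799999999999997 71
73 3 143.21652758426606 -27.096070949131466 -78.058068947693499 0.40799999999999997 56
74 3 146.77169374658587 -33.209301500588857 -84.155570775260557 0.40799999999999997 73
75 3 149.60052135853181 -39.861263140766134 -90.066532070486716 0.40799999999999997 74
76 3 151.79875802140421 -46.65883178896469 -96.079113778970267 0.40799999999999997 75
77 3 -15.619413076332574 124.82256176596934 -61.031125764475483 0.40799999999999997 61
78 3 -20.785031838767392 128.82383410723187 -70.351350906864823 0.40799999999999997 77
79 3 -26.443765466174689 133.46873341128543 -79.067086013087959 0.40799999999999997 78
80 3 -12.246295770789901 122.64484349723919 -61.714217827280152 0.40799999999999997 61
81 3 -15.422685568954888 124.74273662036875 -70.746029148072481 0.40799999999999997 80
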