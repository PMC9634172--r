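specimen_id,cell_id,x_um,y_um,nuclear_area_um2,CD4,CD8,FOXP3,Ki67,PD1,CK
synthetic_demo,c000001,325.5522237159312,357.3059583082795,107.02235210808213,4.0532615005197785,4.3852518653608215,4.046993921266499,2.8008396677895626,2.19595612014993,21.92129918646927
synthetic_demo,c000002,152.3248734883964,325.62530180439353,67.19981744909435,4.191499616128872,5.100191520476665,3.3930141618794654,2.3731024345356384,2.1568617792109688,43.74716676979169
synthetic_demo,c000003,183.04286049678922,277.5645697489381,68.22643827678789,3.4632513268106035,3.1999185519460998,2.953409349506242,2.7586903822537794,2.74638077374188,34.28592129201409
synthetic_demo,c000004,216.283018887043,337.4808955937624,107.02834200177968,1.9281119357250691,3.1891318765899674,4.251813819474335,5.31183526118636,2.097841803437446,15.555404692239145
synthetic_demo,c000005,266.2719319574535,153.85778406634927,58.215985025582405,2.7131650698549588,2.914112110274581,2.5227487020406723,3.1624057011223314,2.3613926242966508,23.506111695820742
synthetic_demo,c000006,315.1345389895141,212.19100393354893,62.028121222560536,2.1787171308236073,1.9810337084556684,3.7540369198376204,2.1008520915933806,3.914023166698381,9.917717067403693
synthetic_demo,c000007,128.8046097382903,220.86433228105307,27.546451908801863,1.5633440682397002,20.57587839062087,1.5638673694435086,3.5956900815875503,15.424090611530705,3.2643220668082855
synthetic_demo,c000008,223.18412763997912,229.65796571224928,29.908792749506148,32.69052566044976,4.435081518389806,36.94139755063661,1.756949290113392,1.9937612404535476,3.3383610277434417
synthetic_demo,c000009,222.34403314068913,300.8106879889965,27.64322214932819,3.174582490736428,3.1393293462799488,1.4904039422987876,2.4875989919835706,9.121987503610969,2.3881717707331265
synthetic_demo,c000010,285.90860068798065,126.31480572745204,27.129228708191633,4.832392211773714,2.9916907254901752,2.075592728918236,3.420123616148757,2.05343294534928,1.796477736425025
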