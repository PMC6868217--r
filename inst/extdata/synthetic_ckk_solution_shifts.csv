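"residue_id","residue","HN","N","CA"
1474,"ALA",8.542,110.16,51.96
1475,"GLN",7.937,109.06,58.32
1476,"PHE",7.053,117.81,50.04
1477,"VAL",9.57,123.02,60.77
1478,"GLY",9.508,111.79,52.14
1479,"GLY",8.336,115.53,56.21
1480,"GLY",8.042,118.91,62.87
1481,"ARG",7.143,105.52,56.16
1482,"LEU",7.538,128.01,58.48
1483,"ILE",8.408,125.12,52.74
1484,"ASN",9.07,130.64,53.04
1485,"PHE",8.432,121.97,49.22
1486,"TYR",7.2,110.38,47.92
1487,"ALA",9.471,112.51,54.77
1488,"TYR",8.683,130.91,51.45
1489,"ASN",7.717,120.27,48.46
1490,"GLU",8.679,124.85,61.9
1491,"LEU",7.671,130.16,58.51
1492,"VAL",9.485,129.38,62.68
1494,"GLN",9.057,114.43,62.29
1495,"ARG",7.364,110.33,47.69
1496,"TYR",9.397,111.7,54.24
1497,"LYS",7.504,105.79,59.19
1498,"ALA",7.77,122.4,63.53
1499,"VAL",7.792,121.07,50.49
1500,"ASN",8.768,104.46,52.99
1501,"ASP",7.746,116.78,63.6
1502,"TYR",7.055,123.24,62.5
1503,"PHE",9.105,116.91,64.85
1504,"LEU",7.585,105.27,53.58
1505,"TYR",8.54,114.09,55.97
1506,"TYR",8.601,130.49,52.05
1508,"ASN",7.443,112.73,63.99
1509,"ALA",7.014,126.91,59.28
1510,"GLN",7.448,113.39,52.23
1511,"SER",7.653,124.36,49.81
1512,"TYR",8.594,105.12,63.28
1513,"PHE",8.711,128.61,53.73
1514,"GLY",8.386,113.04,51.23
1515,"ARG",8.465,105.52,63.29
1517,"VAL",7.015,119.64,57.9
1518,"LEU",7.136,111.94,54.82
1521,"TYR",7.522,106.48,50.56
1522,"GLY",9.07,110.47,55.67
1523,"LYS",8.702,115.33,50.99
1524,"ARG",9.171,107.58,45.09
1526,"GLN",9.396,116.25,46.78
1527,"GLY",8.219,108.68,47.1
1528,"GLN",9.284,127.67,64.73
1531,"LEU",7.204,130.45,60.85
1532,"VAL",7.704,106.45,48.89
1533,"THR",9.146,123.01,62.05
1534,"ARG",8.304,111.15,60.58
1536,"GLU",9.308,110.12,49.25
1537,"SER",9.053,130.96,55.24
1538,"PHE",7.518,104.06,51.22
1539,"LEU",9.306,118.83,65.98
1540,"ASN",7.731,119.6,64.03
1541,"ARG",8.398,109.17,62.23
1542,"LYS",7.809,112.75,53.52
1543,"GLU",7.625,125.46,49.59
1544,"ALA",7.504,123.7,48.88
1545,"SER",8.274,115.76,53.51
1546,"PHE",7.607,126.81,64.64
1547,"GLN",7.173,124.21,60.82
1548,"SER",7.055,109.23,60.96
1549,"ARG",7.533,128.67,48.55
1550,"GLY",8.092,114.49,47.4
1551,"LEU",9.444,109.66,44.08
1552,"ARG",8.466,125.26,51.09
1553,"ALA",9.534,106.71,52.17
1554,"ASN",7.104,106.94,51.35
1556,"GLN",8.01,124.87,48.79
1557,"THR",8.847,111.04,60.81
1558,"ASP",7.417,118.5,52.26
1560,"GLY",7.335,128.5,48.88
1561,"ILE",9.124,114.42,44.46
1562,"GLN",8.419,115.47,44.01
1563,"SER",8.497,107.49,58.84
1565,"LYS",8.077,109.23,53.71
1566,"LEU",9.235,125.9,61.7
1567,"ALA",7.225,121.21,49.91
1568,"ARG",8.227,105.91,58.56
1569,"ILE",7.971,113.41,52.68
1570,"SER",7.059,127.45,44.99
1571,"ALA",8.42,112.53,45.95
1572,"ASN",8.131,117.23,63.69
1573,"TYR",9.544,112.92,64.74
1574,"GLN",8.863,118.26,64.94
1575,"LEU",7.523,125.89,48.8
1576,"TYR",8.255,112.98,65.19
1577,"VAL",9.295,116.33,57
1578,"ILE",8.716,115.32,49.42
1579,"PHE",7.195,116.1,65.28
1580,"SER",9.406,110.11,62.34
1581,"ASP",7.451,114.52,52.76
1582,"GLN",7.931,130.21,55.66
1584,"GLU",8.651,117.06,49.57
1585,"THR",7.658,112.25,44.3
1586,"TYR",8.452,120.54,64.9
1587,"LEU",8.801,130.31,46.37
1589,"PHE",9.095,111.46,47.63
1590,"THR",8.713,106.84,46.16
1591,"GLY",9.465,127.14,49.99
1592,"VAL",8.428,124.17,64.53
1593,"TYR",9.576,119.98,49.02
1594,"PHE",7.753,127.57,45.26
1595,"GLN",9.142,120,51.21
1596,"GLN",7.472,120.53,48.54
1599,"ARG",8.565,120.81,53.49
1600,"ASP",9.415,110.48,48.83
1601,"LYS",9.34,120.33,45.45
1602,"GLN",7.13,127.8,46.55
1603,"ASN",7.72,125.65,61.89
1604,"VAL",9.188,129.57,50.15
1605,"PHE",9.131,112.03,55.63
1606,"ILE",9.078,114.94,63.18
1607,"ILE",8.919,120.07,65.36
1608,"VAL",7.016,113.71,46.76
1609,"ILE",9.012,122.28,51.87
1610,"TYR",7.136,114.93,53.15
1611,"THR",9.04,128.12,56.51
1612,"GLN",7.336,130.56,62.9
1613,"LEU",9.283,120.4,64.76
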