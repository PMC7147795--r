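# 6-hourly best-track fixes, Arabian Sea cyclone, Nov-Dec 2017 (JTWC-style)
# columns: lat (degN), lon (degE), time (MM/DD/HH UTC), msw (m/s)
lat,lon,time,msw
5.9,80.8,11/29/06,12.5
6.2,79.7,11/29/12,12.5
6.7,78.8,11/29/18,15
7.2,77.9,11/30/00,17.5
7.8,76.6,11/30/06,22.5
8.1,75.8,11/30/12,22.5
8.5,74.9,11/30/18,22.5
8.7,74.2,12/01/00,27.5
8.8,73.3,12/01/06,32.5
9.2,72.8,12/01/12,32.5
9.4,72.1,12/01/18,35
9.3,71.5,12/02/00,37.5
9.8,71,12/02/06,42.5
10.5,70.3,12/02/12,42.5
11.1,69.7,12/02/18,42.5
11.7,69.2,12/03/00,42.5
12.3,68.9,12/03/06,37.5
12.9,68.7,12/03/12,37.5
13.5,68.5,12/03/18,37.5
14.5,68.5,12/04/00,35
14.7,68.7,12/04/06,32.5
15.5,69.2,12/04/12,30
16.6,70.0,12/04/18,27.5
17.7,70.9,12/05/00,22.5
18.3,71.5,12/05/06,22.5
18.5,71.4,12/05/12,15
19.2,71.9,12/05/18,10
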