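subject,image,label,length_px,timepoint,known_length_m,drone,timestamp,focal_length_mm,sensor_width_mm,image_width_px,image_height_px,barometer_alt_m,lidar_alt_m,launch_height_m,lens_offset_m
cal_obj,drone1_cal_001,CAL,76.8050831416894,t0,1,drone1,,8.8,13.2,5472,3648,50.6242205740557,,0,0
cal_obj,drone1_cal_002,CAL,73.8087416653651,t0,1,drone1,,8.8,13.2,5472,3648,52.5518466786153,,0,0
cal_obj,drone1_cal_003,CAL,147.986598949972,t0,1,drone1,,8.8,13.2,5472,3648,28.438548778064,,0,0
cal_obj,drone1_cal_004,CAL,92.4541924878659,t0,1,drone1,,8.8,13.2,5472,3648,41.5154084635478,,0,0
cal_obj,drone1_cal_005,CAL,88.9242227585591,t0,1,drone1,,8.8,13.2,5472,3648,49.5300541162541,,0,0
cal_obj,drone1_cal_006,CAL,89.8281366793554,t0,1,drone1,,8.8,13.2,5472,3648,39.7247118458261,,0,0
cal_obj,drone1_cal_007,CAL,82.950963777063,t0,1,drone1,,8.8,13.2,5472,3648,47.1871575131095,,0,0
cal_obj,drone1_cal_008,CAL,227.332191628846,t0,1,drone1,,8.8,13.2,5472,3648,16.0560935262046,,0,0
cal_obj,drone1_cal_009,CAL,242.372727244171,t0,1,drone1,,8.8,13.2,5472,3648,17.2104335817211,,0,0
cal_obj,drone1_cal_010,CAL,91.8376148346328,t0,1,drone1,,8.8,13.2,5472,3648,43.868636962407,,0,0
cal_obj,drone1_cal_011,CAL,124.791832166111,t0,1,drone1,,8.8,13.2,5472,3648,31.6337208091996,,0,0
cal_obj,drone1_cal_012,CAL,131.874433050564,t0,1,drone1,,8.8,13.2,5472,3648,29.3291522593343,,0,0
whale01,drone1_whale01_img01,TL,1012.96586893218,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W10,80.5058633867455,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W20,130.203269670626,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W30,172.978290033638,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W40,204.735013068361,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W50,236.650666778538,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W60,227.545807224622,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W70,174.764708002967,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W80,144.033830389157,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img01,W90,75.805028130894,t0,,drone1,,8.8,13.2,5472,3648,40.0538922225915,,0,0
whale01,drone1_whale01_img02,TL,766.137617952444,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W10,56.7590875216236,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W20,96.9143834049052,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W30,139.499528168964,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W40,146.687911178715,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W50,176.90464249647,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W60,167.599493138797,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W70,129.347582888583,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W80,104.392772995091,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale01,drone1_whale01_img02,W90,61.6955035203432,t0,,drone1,,8.8,13.2,5472,3648,54.2250927770049,,0,0
whale02,drone1_whale02_img01,TL,999.482153964118,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W10,76.5535632157356,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W20,135.348975937062,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W30,187.809194944834,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W40,208.529051826564,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W50,220.239175604286,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W60,215.043115857375,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W70,162.33313777062,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W80,134.477141027179,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img01,W90,94.5453481743587,t0,,drone1,,8.8,13.2,5472,3648,43.6385214590014,,0,0
whale02,drone1_whale02_img02,TL,844.709588651011,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W10,59.9873860228315,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W20,112.366179713126,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W30,152.465436900707,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W40,174.195099897927,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W50,179.035277356878,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W60,160.930796567341,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W70,131.682872246602,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W80,124.451835510517,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
whale02,drone1_whale02_img02,W90,61.8246066930001,t0,,drone1,,8.8,13.2,5472,3648,53.531333613419,,0,0
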