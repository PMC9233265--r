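participant_id,timestamp,steps,heart_rate,intensity
1001,2021-06-07T16:58:00,0,78,sedentary
1001,2021-06-07T16:59:00,12,85,light
1001,2021-06-07T17:00:00,0,102,light
1001,2021-06-07T17:01:00,75,118,moderate
1001,2021-06-07T17:02:00,140,150,vigorous
1001,2021-06-07T17:03:00,8,96,light
1001,2021-06-07T17:04:00,0,79,sedentary
1001,2021-06-07T17:05:00,33,101,light
1001,2021-06-07T17:06:00,61,125,moderate
1001,2021-06-07T17:07:00,0,88,sedentary
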