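Id,ActivityMinute,Steps
1001,6/7/2021 4:58:00 PM,0
1001,6/7/2021 4:59:00 PM,12
1001,6/7/2021 5:00:00 PM,0
1001,6/7/2021 5:01:00 PM,75
1001,6/7/2021 5:02:00 PM,140
1001,6/7/2021 5:03:00 PM,8
1001,6/7/2021 5:04:00 PM,0
1001,6/7/2021 5:05:00 PM,33
1001,6/7/2021 5:06:00 PM,61
1001,6/7/2021 5:07:00 PM,0
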