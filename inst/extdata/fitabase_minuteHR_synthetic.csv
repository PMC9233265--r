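Id,ActivityMinute,Value
1001,6/7/2021 4:58:00 PM,78
1001,6/7/2021 4:59:00 PM,85
1001,6/7/2021 5:00:00 PM,102
1001,6/7/2021 5:01:00 PM,118
1001,6/7/2021 5:02:00 PM,150
1001,6/7/2021 5:03:00 PM,96
1001,6/7/2021 5:04:00 PM,79
1001,6/7/2021 5:05:00 PM,101
1001,6/7/2021 5:06:00 PM,125
1001,6/7/2021 5:07:00 PM,88
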