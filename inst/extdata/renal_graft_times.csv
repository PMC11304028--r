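time
0.0035
0.0068
0.0101
0.0167
0.0168
0.0197
0.0213
0.0233
0.0234
0.0508
0.0508
0.0533
0.0633
0.0767
0.0768
0.0770
0.1066
0.1267
0.1300
0.1639
0.1803
0.1867
0.2180
0.2967
0.3328
0.3700
0.3803
0.4867
0.6233
0.6367
0.6600
0.7180
0.7800
0.7967
0.8016
0.8300
0.8410
0.9100
0.9233
1.0541
1.0607
1.0633
1.1067
1.2213
1.2508
1.2533
1.3800
1.4267
1.4475
1.4500
1.5213
1.5333
1.5525
1.5533
1.5541
1.5934
1.6200
1.6300
1.6344
1.6600
1.7033
1.7067
1.7475
1.7667
1.7700
1.7967
1.8115
1.8933
1.8934
1.9508
1.9733
2.0180
2.0900
2.1167
2.1233
2.2100
2.2148
2.2267
2.2500
2.2533
2.3738
2.4082
2.4180
2.4705
2.5213
2.5705
3.1934
3.2180
3.2367
3.2705
3.3148
3.3567
3.4836
3.4869
3.6213
3.9410
3.9433
4.0001
4.1733
4.1734
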