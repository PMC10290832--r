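group,value
Khiri Rat Nikhom,1.0289
Khiri Rat Nikhom,1.0289
Khiri Rat Nikhom,1.1832
Khiri Rat Nikhom,0.9774
Khiri Rat Nikhom,0.926
Khiri Rat Nikhom,0.6688
Khiri Rat Nikhom,0.7717
Khiri Rat Nikhom,0.7717
Khiri Rat Nikhom,0.8231
Khiri Rat Nikhom,0.8746
Khiri Rat Nikhom,1.0803
Khiri Rat Nikhom,0.8746
Khiri Rat Nikhom,1.0803
Khiri Rat Nikhom,0.926
Khiri Rat Nikhom,1.0289
Khiri Rat Nikhom,0.8231
Khiri Rat Nikhom,0.6688
Khiri Rat Nikhom,0.9774
Khiri Rat Nikhom,1.2347
Khiri Rat Nikhom,0.7717
Khiri Rat Nikhom,0.9774
Khiri Rat Nikhom,0.7202
Khiri Rat Nikhom,1.1832
Khiri Rat Nikhom,1.0289
Khiri Rat Nikhom,0.7717
Khiri Rat Nikhom,0.6688
Khiri Rat Nikhom,0.9774
Khiri Rat Nikhom,0.8746
Khiri Rat Nikhom,1.0803
Khiri Rat Nikhom,1.0803
Khiri Rat Nikhom,0.7717
Khiri Rat Nikhom,0.8746
Khiri Rat Nikhom,0.8746
Khiri Rat Nikhom,0.8746
Khiri Rat Nikhom,0.6688
Khiri Rat Nikhom,0.5659
Khiri Rat Nikhom,0.9774
Khiri Rat Nikhom,0.6173
Khiri Rat Nikhom,0.7202
Khiri Rat Nikhom,0.6173
Khiri Rat Nikhom,0.8231
Khiri Rat Nikhom,0.7202
Khiri Rat Nikhom,0.5659
Khiri Rat Nikhom,0.5144
Khiri Rat Nikhom,0.5144
Khiri Rat Nikhom,0.6173
Khiri Rat Nikhom,0.6688
Khiri Rat Nikhom,0.5659
Khiri Rat Nikhom,0.6173
Khiri Rat Nikhom,0.4116
Koh Samui,0.9774
Koh Samui,0.7717
Koh Samui,0.5659
Koh Samui,0.5659
Koh Samui,1.2347
Koh Samui,1.2347
Koh Samui,1.3376
Koh Samui,0.926
Koh Samui,0.9774
Koh Samui,1.0289
Koh Samui,0.5659
Koh Samui,0.7717
Koh Samui,0.463
Koh Samui,0.5144
Koh Samui,1.389
Koh Samui,1.2861
Koh Samui,1.3376
Koh Samui,1.0289
Koh Samui,1.2347
Koh Samui,1.1318
Koh Samui,0.6173
Koh Samui,0.9774
Koh Samui,0.926
Koh Samui,0.8746
Koh Samui,1.4919
Koh Samui,1.2347
Koh Samui,1.6462
Koh Samui,1.1832
Koh Samui,1.2347
Koh Samui,1.1318
Koh Samui,0.2572
Koh Samui,0.7202
Koh Samui,0.8231
Koh Samui,0.9774
Koh Samui,1.2347
Koh Samui,1.389
Koh Samui,1.7491
Koh Samui,1.2347
Koh Samui,1.2347
Koh Samui,1.1832
Koh Samui,0.6688
Koh Samui,1.2347
Koh Samui,0.8746
Koh Samui,1.0803
Koh Samui,1.2861
Koh Samui,1.1318
Koh Samui,1.852
Koh Samui,1.0803
Koh Samui,1.2347
Koh Samui,1.3376
Kanchanadit,0.2572
Kanchanadit,0.3601
Kanchanadit,0.6173
Kanchanadit,1.0289
Kanchanadit,0.926
Kanchanadit,0.4116
Kanchanadit,0.9774
Kanchanadit,0.8746
Kanchanadit,0.926
Kanchanadit,0.8746
Kanchanadit,0.2572
Kanchanadit,0.3601
Kanchanadit,0.5659
Kanchanadit,0.8231
Kanchanadit,1.1318
Kanchanadit,0.7202
Kanchanadit,0.8231
Kanchanadit,1.1318
Kanchanadit,1.389
Kanchanadit,0.8231
Kanchanadit,0.2572
Kanchanadit,0.3601
Kanchanadit,0.7202
Kanchanadit,0.8231
Kanchanadit,0.7202
Kanchanadit,0.5659
Kanchanadit,1.1832
Kanchanadit,1.0289
Kanchanadit,1.0289
Kanchanadit,1.2861
Kanchanadit,0.1029
Kanchanadit,0.463
Kanchanadit,0.7202
Kanchanadit,0.6173
Kanchanadit,0.6173
Kanchanadit,0.6173
Kanchanadit,1.2347
Kanchanadit,0.8231
Kanchanadit,0.463
Kanchanadit,0.5659
Kanchanadit,0.1543
Kanchanadit,0.3087
Kanchanadit,0.3087
Kanchanadit,0.3601
Kanchanadit,0.3087
Kanchanadit,0.463
Kanchanadit,0.8746
Kanchanadit,0.6173
Kanchanadit,0.3087
Kanchanadit,0.2572
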