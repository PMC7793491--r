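model,region,temperature,rmsd
CCCT3,whole,280,1.8
CCCT3,whole,300,1.9
CCCT3,whole,320,2.1
CCCT3,whole,340,2.1
CCCT3,whole,360,2.4
CCCT3,core,280,1.2
CCCT3,core,300,1.3
CCCT3,core,320,1.2
CCCT3,core,340,1.2
CCCT3,core,360,1.2
CCCT3,loop,280,3.5
CCCT3,loop,300,4.2
CCCT3,loop,320,4.4
CCCT3,loop,340,4.5
CCCT3,loop,360,4.5
CCCT5,whole,280,3.8
CCCT5,whole,300,3.3
CCCT5,whole,320,3.0
CCCT5,whole,340,3.1
CCCT5,whole,360,4.0
CCCT5,core,280,1.2
CCCT5,core,300,1.1
CCCT5,core,320,1.3
CCCT5,core,340,1.0
CCCT5,core,360,1.2
CCCT5,loop,280,6.1
CCCT5,loop,300,4.9
CCCT5,loop,320,5.6
CCCT5,loop,340,5.9
CCCT5,loop,360,6.4
CCCT7,whole,280,5.3
CCCT7,whole,300,4.6
CCCT7,whole,320,4.1
CCCT7,whole,340,5.4
CCCT7,whole,360,5.8
CCCT7,core,280,1.5
CCCT7,core,300,2.6
CCCT7,core,320,1.9
CCCT7,core,340,1.3
CCCT7,core,360,1.4
CCCT7,loop,280,7.0
CCCT7,loop,300,6.2
CCCT7,loop,320,5.9
CCCT7,loop,340,8.7
CCCT7,loop,360,7.7
CCCT6,whole,280,3.5
CCCT6,whole,300,3.4
CCCT6,whole,320,4.3
CCCT6,whole,340,4.6
CCCT6,whole,360,4.8
CCCT6,core,280,1.5
CCCT6,core,300,0.9
CCCT6,core,320,1.0
CCCT6,core,340,2.3
CCCT6,core,360,1.1
CCCT6,loop,280,5.3
CCCT6,loop,300,5.4
CCCT6,loop,320,5.9
CCCT6,loop,340,7.2
CCCT6,loop,360,7.1
CCCTA2,whole,280,1.9
CCCTA2,whole,300,1.9
CCCTA2,whole,320,2.1
CCCTA2,whole,340,2.5
CCCTA2,whole,360,2.2
CCCTA2,core,280,1.4
CCCTA2,core,300,1.3
CCCTA2,core,320,1.3
CCCTA2,core,340,1.3
CCCTA2,core,360,1.5
CCCTA2,loop,280,4.0
CCCTA2,loop,300,4.3
CCCTA2,loop,320,4.4
CCCTA2,loop,340,4.8
CCCTA2,loop,360,5.1
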