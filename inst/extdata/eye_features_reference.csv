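eye,w1,w2,w3,class
1,37.2,2.5,17.0,1
2,15.0,3.2,16.8,2
3,13.1,4.3,22.0,2
4,25.6,5.0,19.5,2
5,20.2,28.6,28.6,3
6,13.9,16.3,30.6,3
7,38.2,3.2,24.2,1
8,48.4,20.3,25.1,4
9,21.0,25.5,25.6,3
10,20.7,5.2,23.9,2
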