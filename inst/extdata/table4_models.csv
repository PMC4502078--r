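term,Baseline,N1,N2,N3,C3Sq
Constant,0.8685,0.9830,0.8865,0.9279,0.8921
MO2,-0.1350,-0.1437,-0.1084,-0.1442,-0.1395
MO3,-0.3874,-0.4061,-0.3725,-0.3749,-0.4325
SC2,-0.0975,-0.1061,-0.0766,-0.0876,-0.0911
SC3,-0.1614,-0.1802,-0.1581,-0.1394,-0.2023
UA2,-0.0764,-0.0850,-0.0613,-0.0475,-0.0674
UA3,-0.0988,-0.1176,-0.1070,-0.0673,-0.1322
PD2,-0.0495,-0.0650,-0.0289,-0.0587,-0.0523
PD3,-0.1390,-0.1510,-0.1362,-0.1265,-0.1807
AD2,-0.0410,-0.0426,-0.0202,-0.0494,-0.0420
AD3,-0.0849,-0.1108,-0.0816,-0.0720,-0.1282
N1,,-0.0831,,,
N2,,,-0.0709,,
N3,,,,-0.1119,
C3Sq,,,,,0.0100
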