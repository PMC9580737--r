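sample_id,IL1B,IL6,IL8,IL17A,CXCL10,TNFA
S0001,6.253305801654788,0.06588782061311438,3.1351078919577224,0.03120736793961781,4.351072791834965,4.639861626850747
S0002,2.94172595053766,0.09172863026944686,4.072395801064647,0.07715539215841356,2.4971193137118832,3.404302395411438
S0003,3.2626172838188707,0.03775571791909998,2.3586793948886084,0.072615611273018,2.686540958882173,4.073939704855392
S0004,2.1334696028956386,0.10577975865828083,8.546067405795982,0.03545466118593023,4.479401106545343,3.2169002153138986
S0005,0.872658050110812,0.10451446559325255,0.8516568566075681,0.019693646605110367,1.369550066447635,0.7179719522860143
S0006,1.9843750641044393,0.04501409096104408,0.9925023844084264,0.04979277020738549,0.8613047942282267,1.2149411829331769
S0007,0.7703463719822392,0.06452314355976374,1.2000190811107898,0.03131639625273166,0.8145294778715765,0.41617794537528047
S0008,1.053122082782375,0.07894385472037216,1.2093189166606924,0.01785054410426115,0.7404304713129165,1.071284259157778
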