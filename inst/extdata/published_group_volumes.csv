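species,age,region,mono_volume_um3,bi_volume_um3,published_percent_larger
mouse,weanling,LV+S,5634,8007,42.1
mouse,weanling,RV,6651,14763,122
mouse,adult,LV+S,16851,23845,41.5
mouse,adult,RV,13116,15154,15.5
rabbit,weanling,LV+S,6063,9015,48.6
rabbit,weanling,RV,6699,11347,69.4
rat,adult,LV+S,18006,25453,41.4
rat,adult,RV,16100,21662,34.5
sheep,fetal,LV+S,3417,5522,61.6
sheep,fetal,RV,5278,10152,92.3
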