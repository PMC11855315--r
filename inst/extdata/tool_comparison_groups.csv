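method,parameter,mean_of_averages,std_of_averages,mean_of_stds
imagej,area,2313.2,581.6,1399.4
imagej,perimeter,172.6,24.0,52.0
imagej,orientation,111.8,5.2,24.0
imagej,time,30.0,6.1,6.1
automated,area,1728.8,302.6,1652.2
automated,perimeter,214.0,24.3,139.4
automated,orientation,101.0,1.6,37.2
automated,time,31.0,13.4,13.4
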