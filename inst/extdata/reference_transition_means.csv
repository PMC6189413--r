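experiment,transition,prev_correspondence,correspondence,mean_ms,sd_ms
cooperative,Nogo/go,C,C,334,41
cooperative,Nogo/go,C,NC,358,42
cooperative,Nogo/go,NC,C,350,40
cooperative,Nogo/go,NC,NC,341,41
cooperative,Go/go,C,C,342,43
cooperative,Go/go,C,NC,348,38
cooperative,Go/go,NC,C,341,37
cooperative,Go/go,NC,NC,345,37
competitive,Nogo/go,C,C,310,33
competitive,Nogo/go,C,NC,332,
competitive,Nogo/go,NC,C,327,31
competitive,Nogo/go,NC,NC,316,33
competitive,Go/go,C,C,320,35
competitive,Go/go,C,NC,326,35
competitive,Go/go,NC,C,320,35
competitive,Go/go,NC,NC,322,36
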