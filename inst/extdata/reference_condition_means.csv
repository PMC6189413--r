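experiment,condition,correspondence,mean_ms,sd_ms
cooperative,individual,NC,347,44
cooperative,individual,C,345,45
cooperative,joint,NC,350,42
cooperative,joint,C,340,42
competitive,individual,NC,342,45
competitive,individual,C,337,41
competitive,joint,NC,307,27
competitive,joint,C,303,28
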