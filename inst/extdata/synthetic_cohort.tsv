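id	host	region	group
seq001_polyprotein	synthetic_host	polyprotein	cladeA
seq002_polyprotein	synthetic_host	polyprotein	cladeA
seq003_polyprotein	synthetic_host	polyprotein	cladeA
seq004_polyprotein	synthetic_host	polyprotein	cladeB
seq005_polyprotein	synthetic_host	polyprotein	cladeB
seq006_polyprotein	synthetic_host	polyprotein	cladeB
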