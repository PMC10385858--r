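record_id	group	intervals	exclusions
low-AT3_01	low-AT3	1-1503	
low-AT3_02	low-AT3	1-1503	
high-AT3_01	high-AT3	1-1503	
high-AT3_02	high-AT3	1-1503	
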