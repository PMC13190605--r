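name	pattern	tail
motif1	Dx(D/N)xDGxxD	
motif2	DxDxNxxxD	
motif3	DxD/NxDxxxxxxD/E	
MIDAS	DxSxS	T:+6..+40;D:+7..+80
RGD	RGD	
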