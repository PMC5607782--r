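Dr.	O
Verghese	SENS
saw	O
Ms.	O
Park	SENS
at	O
Mercy	O
Hospital	O
on	O
Tuesday	O
.	O
He	SENS
remained	O
stable	O
;	O
He	O
was	O
seen	O
by	O
White	SENS
in	O
Austin	O
with	O
nurse	O
Day	SENS
.	O
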