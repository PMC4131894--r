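tissue	total_raw	total_clean	mirna_total
leaf	11752747	10992174	832571
bark	11491921	11273911	1130016
male_flower	10513612	10134148	2359403
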