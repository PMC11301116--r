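era,reversal_class,n
BP,neostigmine,775266
BP,sugammadex,417266
BP,spontaneous,451838
BC,neostigmine,307727
BC,sugammadex,311227
BC,spontaneous,201124
EC,neostigmine,67321
EC,sugammadex,92709
EC,spontaneous,49421
MC,neostigmine,94181
MC,sugammadex,138148
MC,spontaneous,68462
LC,neostigmine,167075
LC,sugammadex,321268
LC,spontaneous,139854
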