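alias	canonical_string
t1	((((Baikal,Shoveler),Pekin),(Steamer1,Steamer2)),Muscovy)
t2	(((Baikal,Shoveler),(Pekin,(Steamer1,Steamer2))),Muscovy)
t3	((((Baikal,Shoveler),(Steamer1,Steamer2)),Pekin),Muscovy)
tree-1	((((Baikal,Shoveler),Pekin),(Steamer1,Steamer2)),Muscovy)
tree-2	(((Baikal,Shoveler),(Pekin,(Steamer1,Steamer2))),Muscovy)
tree-3	((((Baikal,Shoveler),(Steamer1,Steamer2)),Pekin),Muscovy)
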