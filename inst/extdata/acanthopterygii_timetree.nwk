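((((Takifugu:96,Tetraodon:96)tetraodontidae#96:94,(medaka:110,stickleback:110)smegmamorpha#110:80)acanthopterygii#190:130,zebrafish:320)acanthopterygii_stem#320:130,tetrapods:450)root#450;
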