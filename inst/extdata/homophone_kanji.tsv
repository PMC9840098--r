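char	alternatives
浩	宏,弘
伸	信,慎
明	昭,亮
井	伊
加	佳,嘉
健	賢,謙
正	政,昌
美	実
由	裕
幸	行
川	河
田	多
中	仲
本	元
岡	丘
谷	屋
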