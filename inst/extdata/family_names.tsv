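kanji	kana
佐藤	サトウ
鈴木	スズキ
高橋	タカハシ
田中	タナカ
伊藤	イトウ
渡辺	ワタナベ
山本	ヤマモト
中村	ナカムラ
小林	コバヤシ
加藤	カトウ
吉田	ヨシダ
山田	ヤマダ
佐々木	ササキ
山口	ヤマグチ
松本	マツモト
井上	イノウエ
木村	キムラ
林	ハヤシ
斎藤	サイトウ
清水	シミズ
山崎	ヤマザキ
森	モリ
池田	イケダ
橋本	ハシモト
阿部	アベ
石川	イシカワ
中島	ナカジマ
前田	マエダ
藤田	フジタ
後藤	ゴトウ
小川	オガワ
岡田	オカダ
村上	ムラカミ
長谷川	ハセガワ
近藤	コンドウ
石井	イシイ
斉藤	サイトウ
坂本	サカモト
遠藤	エンドウ
藤井	フジイ
青木	アオキ
福田	フクダ
三浦	ミウラ
西村	ニシムラ
藤原	フジワラ
太田	オオタ
松田	マツダ
原田	ハラダ
岡本	オカモト
中野	ナカノ
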